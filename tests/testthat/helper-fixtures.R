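## Shared fixtures, all built in code.

## A small cube with float32-representable values (k/256), so float32
## round trips are bit-exact.
smallCube <- function(h = 4, w = 4, b = 3, mode = "reflectance",
                      seed = 1) {
  set.seed(seed)
  vals <- sample(0:256, h * w * b, replace = TRUE) / 256
  HyperspectralCube(array(vals, c(h, w, b)),
                    BandAxis(n = b, start = 500, step = 10), mode = mode)
}

## Desk-scale synthetic config for fast tests.
tinyConfig <- function(n = 6, seed = 1, ...) {
  SyntheticConfig(nSamples = n, seed = seed, ...)
}

## A tiny SE-ResNet spec for fast network tests.
tinySpec <- function(input = c(9L, 9L, 3L)) {
  ArchitectureSpec(stageBlocks = c(1L, 1L, 1L, 1L),
                   stageChannels = c(8L, 8L, 16L, 16L),
                   stemChannels = 4L, reduction = 4L,
                   headWidths = c(16L, 8L, 5L),
                   inputShape = input)
}

## An 8-plate generator toy set plus a reduced network sized for it;
## used for optimization sanity checks.
toyGeneratorSet <- function(n = 8, seed = 5) {
  ds <- generateDataset(tinyConfig(n = n, seed = seed))
  list(patches = patches(ds$samples),
       Y = concentrations(ds$samples))
}

toySpec <- function() {
  ArchitectureSpec(stageBlocks = c(1L, 1L, 1L, 1L),
                   stageChannels = c(32L, 64L, 128L, 256L),
                   stemChannels = 16L, reduction = 16L,
                   headWidths = c(256L, 64L, 5L),
                   inputShape = c(8L, 8L, 128L))
}
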