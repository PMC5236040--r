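## Shared fixtures: analytic-oracle disks, desk-scale configurations, and a
## memoised full-scale study shared by the heavier tests.

## Antialiased disk (sub-voxel area weighting via supersampling), so that
## projector accuracy tests measure the projector, not the rasterisation.
aaDisk <- function(n = 128L, radiusMm = 25, spacingMm = 1, value = 1,
                   ss = 4L) {
  fineN <- n * ss
  xc <- (seq_len(fineN) - (fineN + 1) / 2) * spacingMm / ss
  fine <- (outer(xc^2, xc^2, "+") <= radiusMm^2) * 1
  disk <- matrix(0, n, n)
  for (i in seq_len(ss)) for (j in seq_len(ss))
    disk <- disk + fine[seq(i, fineN, ss), seq(j, fineN, ss)]
  disk * value / ss^2
}

diskImage <- function(value, semantics, n = 128L, radiusMm = 25,
                      spacingMm = 1, nz = 1L) {
  sl <- aaDisk(n, radiusMm, spacingMm, value)
  voxelImage(array(rep(sl, nz), c(n, n, nz)), spacingMm,
             semantics = semantics)
}

## Analytic chord length through a disk at radial offset s (cm).
chordCm <- function(sMm, radiusMm = 25)
  2 * sqrt(pmax(radiusMm^2 - sMm^2, 0)) / 10

## Desk-scale configuration for reconstruction-chain unit tests.
smallSpec <- function(nz = 6L)
  phantomSpec(grid = c(64L, 64L, nz), spacingMm = 2)

smallGeom <- function(nAngles = 90)
  parallelGeometry(nAngles = nAngles, nRadial = 64L, radialSpacing = 2)

## Full-scale noise-free study (the acceptance-grade simulation), computed
## once per test run and shared between the criteria that need it.
.studyCache <- new.env(parent = emptyenv())

fullStudy <- function() {
  if (is.null(.studyCache$study))
    .studyCache$study <- runPhantomStudy(includeMatched = TRUE)
  .studyCache$study
}
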