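# Shared fixture builders: everything is generated in code at test time.

smallScene <- function(seed = 1, size = 128, ...) {
  syntheticScene(width = size, height = size, seed = seed, ...)
}

truthConfig <- function(...) faConfig(maskSource = "synthetic_truth", ...)

# deterministic hand-built scene: disc lesion, horizontal vessel stripe kept
# away from the lesion so the lesion Score is carried by mottle alone
discScene <- function(size = 128, r = 40, mottleFraction = 0.3, blockR = 0,
                      withVessel = TRUE, noiseSeed = 77) {
  cx <- col(matrix(0, size, size)) - 1
  cy <- row(matrix(0, size, size)) - 1
  c0 <- round(size * 0.55)
  lesion <- ((cx - c0)^2 + (cy - c0)^2) <= r^2
  vessel <- if (withVessel) abs(cy - round(size * 0.12)) <= 1
            else matrix(FALSE, size, size)
  set.seed(noiseSeed)
  noise <- matrix(stats::rnorm(size * size), size, size)
  band <- gaussianBlurReflect(noise, 2) - gaussianBlurReflect(noise, 4.5)
  mottle <- lesion & band > stats::quantile(band[lesion], 1 - mottleFraction)
  if (blockR > 0)
    mottle <- mottle & !(((cx - c0)^2 + (cy - c0)^2) <= blockR^2)
  SyntheticScene(vessel, lesion, mottle, seed = noiseSeed)
}

# independent brute-force scoring oracle: threshold the illumination-free
# rendered intensities at 1.2x their mode and count inside the lesion mask
idealScore <- function(scene, multiplier = 1.2) {
  ideal <- sceneIdealIntensities(scene)
  md <- computeMode(ideal, valid = matrix(TRUE, nrow(ideal), ncol(ideal)))
  sum(ideal > multiplier * md & scene@lesionMask == 1)
}
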