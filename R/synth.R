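#' Default FT-NIR wavenumber grid
#'
#' 1,557 equally spaced points spanning 4,000-10,000 cm^-1 (spacing about
#' 3.856 cm^-1), the grid produced by an FT-NIR diffuse-reflectance scan at
#' 8 cm^-1 resolution over that range.
#' @param n number of points.
#' @return ascending numeric vector of wavenumbers.
#' @export
default_grid <- function(n = 1557L) seq(4000, 10000, length.out = n)

#' Pure-component (endmember) band model
#'
#' An endmember is a pure-component absorbance spectrum modelled as a flat
#' baseline plus a sum of Gaussian absorption bands, the broad-band shape
#' typical of NIR overtone/combination features.
#'
#' @param species one of `"DBT"`, `"CBG"`, `"PBG"`.
#' @param centers band centers, cm^-1, within \[4000, 10000\].
#' @param widths Gaussian sigmas, cm^-1, all positive.
#' @param amplitudes peak absorbances, AU, all positive.
#' @param baseline baseline absorbance level, AU.
#' @return an `endmember_set` object.
#' @export
endmember_set <- function(species, centers, widths, amplitudes, baseline) {
  species <- match.arg(species, c("DBT", "CBG", "PBG"))
  stopifnot(length(centers) == length(widths),
            length(centers) == length(amplitudes),
            all(amplitudes > 0), all(widths > 0),
            all(centers >= 4000 & centers <= 10000),
            baseline >= 0)
  structure(list(species = species,
                 bands = data.frame(center = centers, width = widths,
                                    amplitude = amplitudes),
                 baseline_level = baseline),
            class = "endmember_set")
}

# Key wavenumbers where the blood-food species differ: C-H combination bands
# (fat), C=O / RCO2H overtones (protein, sugar), S-H and aromatic C-H
# (methionine, tyrosine/phenylalanine), and N-H second overtones (amines).
key_wavenumbers <- function() {
  c(4108, 4405, 5238, 5326, 5477, 5774, 6241, 6931, 7189, 8015, 9399, 9997)
}

# Per-species band amplitude tables (AU). Relative strengths track the
# compositional differences between the species: CBG (highest fat) strongest
# at the 4108/4405 C-H bands; PBG (highest protein and sugar) strongest at
# the 5238/5326/5477 C=O region; DBT (highest methionine, aromatic and basic
# amino acids) strongest at 5774 (S-H), 6241 (Ar-CH) and the 9399/9997 N-H
# overtones.
endmember_defaults <- function() {
  list(
    DBT = list(amplitude = c(0.50, 0.46, 0.62, 0.55, 0.40, 0.30,
                             0.22, 0.30, 0.24, 0.16, 0.10, 0.08),
               baseline = 0.35),
    CBG = list(amplitude = c(0.62, 0.58, 0.55, 0.48, 0.34, 0.20,
                             0.16, 0.26, 0.28, 0.19, 0.07, 0.05),
               baseline = 0.30),
    PBG = list(amplitude = c(0.45, 0.41, 0.70, 0.63, 0.47, 0.24,
                             0.18, 0.33, 0.21, 0.13, 0.12, 0.10),
               baseline = 0.40)
  )
}

# Band sigmas (cm^-1): combination bands near 4000-5500 are narrower than the
# first/second overtone bands at higher wavenumbers.
band_widths_default <- function() {
  c(50, 55, 60, 60, 65, 70, 80, 90, 90, 100, 110, 120)
}

#' Default endmembers for the three blood-food species
#'
#' Twelve Gaussian bands at fixed key wavenumbers (4108, 4405, 5238, 5326,
#' 5477, 5774, 6241, 6931, 7189, 8015, 9399, 9997 cm^-1), shared by the three
#' species, with species-specific amplitude and baseline constants so that
#' duck blood tofu and the two adulterant gels are spectrally separable.
#' Deterministic: no randomness is involved.
#'
#' @return named list of three `endmember_set`s (`DBT`, `CBG`, `PBG`).
#' @export
default_endmembers <- function() {
  defs <- endmember_defaults()
  centers <- key_wavenumbers()
  widths <- band_widths_default()
  lapply(stats::setNames(names(defs), names(defs)), function(sp)
    endmember_set(sp, centers, widths, defs[[sp]]$amplitude, defs[[sp]]$baseline))
}

#' Evaluate an endmember on a wavenumber grid
#' @param em an `endmember_set`.
#' @param grid wavenumber vector, cm^-1.
#' @return absorbance vector, same length as `grid`.
#' @export
eval_endmember <- function(em, grid = default_grid()) {
  stopifnot(inherits(em, "endmember_set"))
  b <- em$bands
  g <- outer(grid, b$center, "-")
  drop(exp(-(g^2) / (2 * rep(b$width^2, each = length(grid)))) %*% b$amplitude) +
    em$baseline_level
}

#' Mix endmember spectra by mass fraction
#'
#' Beer-Lambert linear mixing: the absorbance of a mixture is the
#' fraction-weighted sum of the pure-component spectra.
#'
#' @param endmembers list of three `endmember_set`s (DBT, CBG, PBG order).
#' @param fractions length-3 mass-fraction vector summing to 1.
#' @param grid wavenumber vector.
#' @return absorbance vector.
#' @export
mix_spectrum <- function(endmembers, fractions, grid = default_grid()) {
  stopifnot(length(fractions) == 3L)
  if (any(fractions < 0) || any(fractions > 1) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("invalid composition: fractions must lie in [0,1] and sum to 1")
  E <- vapply(endmembers, eval_endmember, numeric(length(grid)), grid = grid)
  drop(E %*% fractions)
}

#' Measurement artifact parameters
#'
#' Parameterizes the per-scan measurement distortions the simulator adds and
#' the scatter-correction pretreatments remove: a multiplicative scatter
#' slope (log-normal), an additive offset, a linear baseline tilt across the
#' grid, and white noise, averaged over `n_replicates` replicate scans of the
#' same sample.
#'
#' @param scatter_slope_sd sd of the log multiplicative slope (unitless).
#' @param scatter_offset_sd sd of the additive offset, AU.
#' @param tilt_sd sd of the linear tilt, AU per cm^-1.
#' @param noise_sd sd of the white noise per channel and replicate, AU.
#' @param n_replicates number of replicate scans averaged (>= 1).
#' @return an `artifact_params` object.
#' @export
artifact_params <- function(scatter_slope_sd = 0.08, scatter_offset_sd = 0.04,
                            tilt_sd = 1e-5, noise_sd = 0.003,
                            n_replicates = 3L) {
  stopifnot(scatter_slope_sd >= 0, scatter_offset_sd >= 0, tilt_sd >= 0,
            noise_sd >= 0, n_replicates >= 1)
  structure(list(scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 tilt_sd = tilt_sd, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates)),
            class = "artifact_params")
}

#' Apply measurement artifacts to a clean spectrum
#'
#' Each replicate scan r draws a multiplicative slope
#' `b_r = exp(N(0, scatter_slope_sd))`, an offset `a_r ~ N(0,
#' scatter_offset_sd)`, a tilt `c_r ~ N(0, tilt_sd)` and white noise, and
#' observes `b_r * x + a_r + c_r * (nu - mean(nu)) + eps`. The returned
#' spectrum is the mean of the replicates, as in triplicate-scan averaging.
#' Reproducible given the seed.
#'
#' @param spectrum clean absorbance vector.
#' @param params an [artifact_params()] object.
#' @param grid wavenumber vector matching `spectrum`.
#' @param seed integer seed for this sample's substream.
#' @return distorted absorbance vector.
#' @export
apply_artifacts <- function(spectrum, params = artifact_params(),
                            grid = default_grid(), seed = 1L) {
  stopifnot(inherits(params, "artifact_params"),
            length(spectrum) == length(grid))
  # all replicates are identical when every sd is zero; averaging them must
  # return the input bit-for-bit
  if (params$scatter_slope_sd == 0 && params$scatter_offset_sd == 0 &&
      params$tilt_sd == 0 && params$noise_sd == 0)
    return(spectrum)
  nu_c <- grid - mean(grid)
  with_seed(seed, {
    acc <- numeric(length(spectrum))
    for (r in seq_len(params$n_replicates)) {
      b <- exp(stats::rnorm(1, 0, params$scatter_slope_sd))
      a <- stats::rnorm(1, 0, params$scatter_offset_sd)
      tilt <- stats::rnorm(1, 0, params$tilt_sd)
      eps <- if (params$noise_sd > 0)
        stats::rnorm(length(spectrum), 0, params$noise_sd) else 0
      acc <- acc + b * spectrum + a + tilt * nu_c + eps
    }
    acc / params$n_replicates
  })
}

# The experimental design: one row per cell, Table-1-style.
design_cells <- function() {
  lev <- seq(0.1, 0.5, by = 0.1)
  rbind(
    data.frame(f_dbt = 1, f_cbg = 0, f_pbg = 0),
    data.frame(f_dbt = 0, f_cbg = 1, f_pbg = 0),
    data.frame(f_dbt = 0, f_cbg = 0, f_pbg = 1),
    data.frame(f_dbt = 1 - lev, f_cbg = lev, f_pbg = 0),
    data.frame(f_dbt = 1 - lev, f_cbg = 0, f_pbg = lev),
    data.frame(f_dbt = 1 - lev, f_cbg = lev / 2, f_pbg = lev / 2)
  )
}

#' Simulate the full adulteration study design
#'
#' Generates the complete sample design: `n_per_cell` samples each of raw
#' DBT, pure CBG and pure PBG, plus `n_per_cell` samples at each of the five
#' adulteration levels (10-50% in 10% steps) for the two binary series and
#' for the ternary series (equal CBG/PBG split). With the default
#' `n_per_cell = 30` this yields 540 samples. Each sample's artifacts are
#' drawn from a per-sample substream of `seed`, so a subset of the design is
#' reproducible independently of the rest.
#'
#' @param endmembers list of three `endmember_set`s.
#' @param params an [artifact_params()] object.
#' @param seed master integer seed.
#' @param n_per_cell samples per design cell (default 30).
#' @param grid wavenumber grid.
#' @return a [spectra_set()].
#' @export
generate_design <- function(endmembers = default_endmembers(),
                            params = artifact_params(), seed = 1L,
                            n_per_cell = 30L, grid = default_grid()) {
  cells <- design_cells()
  frac <- as.matrix(cells[rep(seq_len(nrow(cells)), each = n_per_cell), ])
  n <- nrow(frac)
  E <- vapply(endmembers, eval_endmember, numeric(length(grid)), grid = grid)
  clean <- frac %*% t(E)
  A <- matrix(0, n, length(grid))
  for (i in seq_len(n))
    A[i, ] <- apply_artifacts(clean[i, ], params, grid,
                              seed = substream_seed(seed, "sample", i))
  ids <- sprintf("s%04d", seq_len(n))
  spectra_set(grid, A, ids, frac)
}
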