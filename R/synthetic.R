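#' Constituent basis spectra for the synthetic generator
#'
#' Component bases — lipid, polysaccharide, protein, polyphenol, tannin,
#' plus a broad background envelope standing for the residual dry mass
#' (cell-wall polymers and other organics) that closes the composition —
#' built from Lorentzian (solid-state default) or Gaussian peaks at
#' the chemical shifts where these constituents appear in ¹³C CPMAS spectra
#' of bee pollen: aliphatic lipid chains at 36/30/23/14 ppm with the ester
#' carbonyl near 175 ppm, polysaccharide carbons across 60–110 ppm with
#' anomeric signals at 90–110 ppm, protein aliphatics below 40 ppm plus the
#' amide envelope near 180 ppm, polyphenol aromatics across 100–170 ppm with
#' a split pair at 133/137 ppm, and a broad tannin hump at 140–160 ppm.
#' Widths are 2–8 ppm, mimicking CPMAS line broadening.
#'
#' @return Named list of `component_basis` objects; each has `name` and a
#'   data.frame `peaks` with columns `center`, `width`, `amplitude`, `shape`.
#' @export
default_basis <- function() {
  pk <- function(center, width, amplitude, shape = "lorentzian")
    data.frame(center = center, width = width, amplitude = amplitude,
               shape = shape, stringsAsFactors = FALSE)
  mk <- function(name, peaks)
    structure(list(name = name, peaks = peaks), class = "component_basis")
  list(
    lipid = mk("lipid", rbind(
      pk(36, 2.0, 1.00), pk(30, 2.0, 0.75), pk(23, 2.0, 0.35),
      pk(14, 1.8, 0.30), pk(130, 2.5, 0.20), pk(175, 2.5, 0.35))),
    polysaccharide = mk("polysaccharide", rbind(
      pk(62, 2.0, 0.55), pk(72, 2.0, 1.00), pk(78, 2.0, 0.70),
      pk(98, 2.0, 0.30, "gaussian"), pk(105, 2.0, 0.45, "gaussian"))),
    protein = mk("protein", rbind(
      pk(20, 3.0, 0.30), pk(30, 3.0, 0.40), pk(42, 3.0, 0.45),
      pk(55, 3.5, 0.60), pk(70, 3.5, 0.30), pk(123, 4.0, 0.25),
      pk(165, 4.0, 0.30), pk(180, 5.0, 0.80))),
    polyphenol = mk("polyphenol", rbind(
      pk(95, 3.0, 0.25), pk(115, 3.0, 0.45), pk(128, 3.0, 0.50),
      pk(133, 2.0, 0.65), pk(137, 2.0, 0.60), pk(145, 3.0, 0.40),
      pk(160, 3.0, 0.35), pk(168, 3.0, 0.30))),
    tannin = mk("tannin", rbind(
      pk(145, 8.0, 0.80, "gaussian"), pk(155, 8.0, 1.00, "gaussian"))),
    background = mk("background", rbind(
      pk(33, 12.0, 0.20, "gaussian"), pk(75, 15.0, 1.00, "gaussian"),
      pk(105, 8.0, 0.35, "gaussian"), pk(172, 10.0, 0.20, "gaussian")))
  )
}

#' Evaluate a component basis on a ppm grid
#'
#' Peaks are summed and the curve is normalized to unit mean intensity over
#' the grid, so a composition value multiplies a shape of fixed integrated
#' intensity regardless of how many peaks the component has.
#'
#' @param basis A `component_basis`.
#' @param grid Numeric ppm vector.
#' @return Nonnegative numeric vector, `mean() == 1`.
#' @export
eval_basis <- function(basis, grid) {
  stopifnot(inherits(basis, "component_basis"))
  pks <- basis$peaks
  if (any(pks$width <= 0) || any(pks$amplitude <= 0))
    stop("peak widths and amplitudes must be positive")
  if (any(pks$center < 0 | pks$center > 220))
    stop("peak centers must lie in 0-220 ppm")
  y <- numeric(length(grid))
  for (i in seq_len(nrow(pks))) {
    d <- grid - pks$center[i]
    y <- y + switch(pks$shape[i],
      lorentzian = pks$amplitude[i] * pks$width[i]^2 / (pks$width[i]^2 + d^2),
      gaussian = pks$amplitude[i] * exp(-d^2 / (2 * pks$width[i]^2)),
      stop("unknown peak shape '", pks$shape[i], "'"))
  }
  y / mean(y)
}

#' Generator configuration
#'
#' Defaults describe the study conditions the workflow is exercised under:
#' 35 samples on a 3072-point 220-0 ppm grid, white noise at 1.5% of the
#' peak mean-spectrum intensity (a moderate signal-to-noise ratio for ¹³C
#' CPMAS), and per-sample multiplicative/additive scatter strong enough that
#' MSC and SNV have something real to remove.
#'
#' @param n_samples Number of samples (>= 4).
#' @param grid_points Points on the ppm grid (default 3072).
#' @param ppm_span `c(high, low)` ppm (default `c(220, 0)`).
#' @param noise_sd White-noise sd relative to the maximum of the mean clean
#'   spectrum (default 0.015).
#' @param scatter_slope_sd Sd of the per-sample multiplicative slope around 1
#'   (default 0.04).
#' @param scatter_offset_sd Sd of the per-sample additive offset, relative to
#'   the maximum mean-spectrum intensity (default 0.02).
#' @param tp_scale Scaling from total polyphenols (mg GAE/g) to spectral
#'   loading of the polyphenol basis (default 0.5).
#' @param tannin_share Tannin loading as a fraction of TP (default 0.1).
#' @param ph_s_assoc Multiplier (0..1) on the covariance of pH and S with
#'   the other properties; 1 keeps the associations of the reference table.
#' @param closure If `TRUE` (default) a background component with loading
#'   `100 - (sum of the named constituent loadings)` closes each sample's
#'   composition to 100% of the dry mass, so total spectral intensity is
#'   constant apart from scatter — the regime in which MSC/SNV are the right
#'   corrections, as with real CPMAS intensities whose absolute scale is
#'   arbitrary.
#' @param composition_table `reference_table` whose column means, covariance
#'   and ranges define the composition distribution (default: the packaged
#'   35-sample table).
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_samples = 35L, grid_points = 3072L,
                             ppm_span = c(220, 0), noise_sd = 0.015,
                             scatter_slope_sd = 0.04, scatter_offset_sd = 0.02,
                             tp_scale = 0.5, tannin_share = 0.1,
                             ph_s_assoc = 1.0, closure = TRUE,
                             composition_table = NULL, seed = 1L) {
  if (n_samples < 4L) stop("n_samples must be >= 4")
  if (noise_sd < 0 || scatter_slope_sd < 0 || scatter_offset_sd < 0)
    stop("noise and scatter sds must be >= 0")
  if (grid_points < 2L) stop("grid_points must be >= 2")
  if (length(ppm_span) != 2L || ppm_span[1L] <= ppm_span[2L])
    stop("ppm_span must be c(high, low)")
  structure(list(n_samples = as.integer(n_samples),
                 grid_points = as.integer(grid_points),
                 ppm_span = as.numeric(ppm_span),
                 noise_sd = noise_sd,
                 scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 tp_scale = tp_scale, tannin_share = tannin_share,
                 ph_s_assoc = ph_s_assoc, closure = isTRUE(closure),
                 composition_table = composition_table,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Draw sample compositions matching the reference-table statistics
#'
#' Properties are drawn from a multivariate normal fitted to the reference
#' table (protein excluded — it is recomputed), clipped to the table's
#' per-column ranges. Two hard constraints are then applied: protein is set
#' to exactly 6.25 x N (the Kjeldahl conversion), and ABTS activity is
#' regenerated as an affine function of TP plus Gaussian noise calibrated so
#' the population TP-ABTS Pearson correlation is 0.84.
#'
#' @param cfg A [generator_config].
#' @return A `reference_table` data.frame with `n_samples` rows.
#' @export
sample_compositions <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  tbl <- cfg$composition_table %||% load_reference_table()
  props <- reference_properties()
  base <- setdiff(props, "protein")
  Yt <- as.matrix(tbl[, base])
  mu <- colMeans(Yt)
  S <- stats::cov(Yt)
  if (cfg$ph_s_assoc != 1) {
    for (v in c("ph", "s")) {
      oth <- setdiff(base, v)
      S[v, oth] <- S[v, oth] * cfg$ph_s_assoc
      S[oth, v] <- S[oth, v] * cfg$ph_s_assoc
    }
  }
  set.seed(cfg$seed)
  Z <- MASS::mvrnorm(cfg$n_samples, mu = mu, Sigma = S)
  if (cfg$n_samples == 1L) Z <- matrix(Z, nrow = 1L)
  lo <- apply(Yt, 2L, min); hi <- apply(Yt, 2L, max)
  for (j in seq_along(base)) Z[, j] <- pmin(pmax(Z[, j], lo[j]), hi[j])
  d <- as.data.frame(Z)
  names(d) <- base
  # ABTS as affine-in-TP plus noise, calibrated to r = 0.84 in population
  r_target <- 0.84
  co <- stats::coef(stats::lm(abts ~ tp, data = as.data.frame(tbl)))
  sd_tp <- stats::sd(tbl$tp)
  eps_sd <- abs(co[2L]) * sd_tp * sqrt(1 / r_target^2 - 1)
  d$abts <- co[1L] + co[2L] * d$tp + stats::rnorm(nrow(d), 0, eps_sd)
  d$abts <- pmin(pmax(d$abts, min(tbl$abts)), max(tbl$abts))
  d$protein <- 6.25 * d$n
  out <- data.frame(sample_id = paste0("syn", seq_len(nrow(d))),
                    d[, c("tp", "abts", "reducing_sugars")],
                    protein = d$protein,
                    d[, c("fat", "nhcs", "c", "n", "s", "ph")])
  validate_reference_table(out)
  class(out) <- c("reference_table", "data.frame")
  out
}

#' Synthesize a set of ¹³C CPMAS-like spectra with matching properties
#'
#' Each clean spectrum is a linear mixture of the constituent bases, with
#' loadings taken from the sample's composition: lipid from fat,
#' polysaccharide from reducing sugars, protein from protein, polyphenol
#' from scaled TP, and tannin from a small TP-correlated share. Per-sample
#' multiplicative slope and additive offset emulate scatter-like intensity
#' variation (what MSC/SNV are there to remove), and white Gaussian noise is
#' added per point. pH and sulfur have no direct spectral signature; they
#' enter only through their correlation with the composition.
#'
#' @param cfg A [generator_config].
#' @param basis Component bases as from [default_basis].
#' @param compositions Optional precomputed `reference_table`; default draws
#'   via [sample_compositions] under `cfg$seed`.
#' @return List with `spectra` (a `spectra_matrix`), `refs` (the
#'   `reference_table`) and `clean` (noise- and scatter-free matrix, for
#'   diagnostics).
#' @export
synthesize <- function(cfg, basis = default_basis(), compositions = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  refs <- compositions %||% sample_compositions(cfg)
  if (nrow(refs) != cfg$n_samples)
    stop("compositions have ", nrow(refs), " rows but cfg expects ",
         cfg$n_samples)
  grid <- seq(cfg$ppm_span[1L], cfg$ppm_span[2L],
              length.out = cfg$grid_points)
  Bmat <- vapply(basis, eval_basis, numeric(length(grid)), grid = grid)
  load_mat <- cbind(lipid = refs$fat,
                    polysaccharide = refs$reducing_sugars,
                    protein = refs$protein,
                    polyphenol = cfg$tp_scale * refs$tp,
                    tannin = cfg$tannin_share * refs$tp)
  if (cfg$closure) {
    bg <- 100 - rowSums(load_mat)
    if (any(bg < 0))
      stop("constituent loadings exceed 100%; closure infeasible")
    load_mat <- cbind(load_mat, background = bg)
  }
  lack <- setdiff(colnames(load_mat), colnames(Bmat))
  if (length(lack))
    stop("basis list lacks component(s): ", paste(lack, collapse = ", "))
  clean <- load_mat %*% t(Bmat[, colnames(load_mat)])
  i_max <- max(colMeans(clean))
  n <- nrow(clean); p <- ncol(clean)
  slope <- stats::rnorm(n, 1, cfg$scatter_slope_sd)
  offset <- stats::rnorm(n, 0, cfg$scatter_offset_sd * i_max)
  noise <- matrix(stats::rnorm(n * p, 0, cfg$noise_sd * i_max), n, p)
  X <- clean * slope + offset + noise
  dimnames(X) <- list(refs$sample_id, NULL)
  sm <- structure(list(sample_ids = refs$sample_id, grid = grid, X = X),
                  class = "spectra_matrix")
  list(spectra = sm, refs = refs,
       clean = spectra_matrix_like(sm, clean))
}
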