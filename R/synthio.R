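#' Dual-reporter cytometry generative model
#'
#' Parameter set for the synthetic flow-cytometry event generator. Each
#' singlet cell draws one shared (extrinsic) lognormal factor and one
#' independent (intrinsic) lognormal factor per fluorescence channel, so the
#' intrinsic/extrinsic decomposition of the generated data has known ground
#' truth: for this multiplicative model eta_ext^2 = exp(sigma_ext^2) - 1 and
#' eta_int^2 = exp(sigma_ext^2) * (exp(sigma_int^2) - 1) (equal intrinsic
#' sigmas), which reduce to exp(sigma^2) - 1 per component for small sigma.
#'
#' @param mu_gfp,mu_mcherry Linear-scale mean reporter intensities (a.u.).
#' @param sigma_ext Log-scale SD of the shared extrinsic factor.
#' @param sigma_int_gfp,sigma_int_mcherry Log-scale SDs of the per-channel
#'   intrinsic factors.
#' @param scatter_mu,scatter_sigma Lognormal parameters of FSC-A; SSC-A is
#'   generated log-correlated with FSC-A.
#' @param rho_scatter Correlation of log FSC-A and log SSC-A.
#' @param f_debris,f_doublet Contamination fractions in `[0, 1)`; their sum
#'   must stay below 1.
#' @return An object of class `reporter_model`.
#' @export
reporter_model <- function(mu_gfp = 1000, mu_mcherry = 1000,
                           sigma_ext = 0.20,
                           sigma_int_gfp = 0.15, sigma_int_mcherry = 0.15,
                           scatter_mu = log(5e4), scatter_sigma = 0.25,
                           rho_scatter = 0.7,
                           f_debris = 0, f_doublet = 0) {
  m <- list(mu_gfp = mu_gfp, mu_mcherry = mu_mcherry,
            sigma_ext = sigma_ext,
            sigma_int_gfp = sigma_int_gfp,
            sigma_int_mcherry = sigma_int_mcherry,
            scatter_mu = scatter_mu, scatter_sigma = scatter_sigma,
            rho_scatter = rho_scatter,
            f_debris = f_debris, f_doublet = f_doublet)
  num <- unlist(m)
  if (any(!is.finite(num)))
    stop("reporter_model parameters must be finite")
  if (mu_gfp <= 0 || mu_mcherry <= 0)
    stop("mean intensities must be positive")
  if (sigma_ext < 0 || sigma_int_gfp < 0 || sigma_int_mcherry < 0 ||
      scatter_sigma < 0)
    stop("all sigmas must be >= 0")
  if (f_debris < 0 || f_doublet < 0 || f_debris + f_doublet >= 1)
    stop("contamination fractions must satisfy 0 <= f_debris + f_doublet < 1")
  if (abs(rho_scatter) > 1) stop("rho_scatter must be in [-1, 1]")
  structure(m, class = "reporter_model")
}

# Default FSC-A trigger threshold (a.u.); debris is generated below it.
NV_TRIGGER_DEFAULT <- 2570
# Singlet FSC-W lognormal parameters; doublets get a 1.6-2.2x multiplier.
NV_FSCW_MU <- log(100)
NV_FSCW_SIGMA <- 0.05

#' Construct an event table
#'
#' @param df A data.frame with columns event_id, FSC_A, FSC_W, SSC_A, GFP,
#'   mCherry, and optionally provenance/lineage labels.
#' @param log_channels Character vector of channels already log-transformed.
#' @param log_base Log base used for those channels.
#' @keywords internal
new_event_table <- function(df, log_channels = character(0), log_base = NA_real_) {
  structure(df,
            log_channels = log_channels,
            log_base = log_base,
            gate_log = attr(df, "gate_log"),
            class = c("event_table", "data.frame"))
}

# Draw n singlet cells from the model: shared extrinsic factor, independent
# intrinsic factors, log-correlated FSC-A/SSC-A.
draw_singlets <- function(model, n) {
  E <- stats::rlnorm(n, 0, model$sigma_ext)
  gfp <- model$mu_gfp * E * stats::rlnorm(n, 0, model$sigma_int_gfp)
  mch <- model$mu_mcherry * E * stats::rlnorm(n, 0, model$sigma_int_mcherry)
  z1 <- stats::rnorm(n)
  z2 <- model$rho_scatter * z1 +
    sqrt(max(0, 1 - model$rho_scatter^2)) * stats::rnorm(n)
  fsc <- exp(model$scatter_mu + model$scatter_sigma * z1)
  ssc <- exp(model$scatter_mu - log(2) + model$scatter_sigma * z2)
  fsw <- stats::rlnorm(n, NV_FSCW_MU, NV_FSCW_SIGMA)
  data.frame(FSC_A = fsc, FSC_W = fsw, SSC_A = ssc, GFP = gfp, mCherry = mch)
}

#' Generate a synthetic cytometry event table
#'
#' Singlet fluorescence follows `mu_ch * E * I_ch` with `E` a shared
#' lognormal extrinsic factor and `I_ch` independent per-channel lognormal
#' intrinsic factors. Debris events sit below the FSC-A trigger threshold
#' with near-zero fluorescence; doublet events are sums of two singlet draws
#' with FSC-W inflated by a uniform 1.6-2.2x multiplier, which keeps them
#' separable from singlets by an FSC-W gate.
#'
#' @param model A [reporter_model()].
#' @param n_cells Number of events to generate (>= 1).
#' @param seed Integer seed; identical seeds reproduce identical tables.
#' @return An `event_table` data.frame with columns event_id, FSC_A, FSC_W,
#'   SSC_A, GFP, mCherry, provenance (singlet/debris/doublet).
#' @export
gen_events <- function(model, n_cells, seed) {
  stopifnot(inherits(model, "reporter_model"), n_cells >= 1)
  set.seed(as.integer(seed))
  prov <- sample(c("singlet", "debris", "doublet"), n_cells, replace = TRUE,
                 prob = c(1 - model$f_debris - model$f_doublet,
                          model$f_debris, model$f_doublet))
  n_sing <- sum(prov == "singlet")
  n_deb <- sum(prov == "debris")
  n_dbl <- sum(prov == "doublet")

  out <- data.frame(FSC_A = numeric(n_cells), FSC_W = numeric(n_cells),
                    SSC_A = numeric(n_cells), GFP = numeric(n_cells),
                    mCherry = numeric(n_cells))
  if (n_sing > 0)
    out[prov == "singlet", ] <- draw_singlets(model, n_sing)
  if (n_deb > 0) {
    out[prov == "debris", ] <- data.frame(
      FSC_A = stats::runif(n_deb, 0, NV_TRIGGER_DEFAULT * 0.999),
      FSC_W = stats::rlnorm(n_deb, NV_FSCW_MU - 1, NV_FSCW_SIGMA),
      SSC_A = stats::rlnorm(n_deb, log(50), 0.5),
      GFP = stats::rlnorm(n_deb, log(2), 0.5),
      mCherry = stats::rlnorm(n_deb, log(2), 0.5))
  }
  if (n_dbl > 0) {
    a <- draw_singlets(model, n_dbl)
    b <- draw_singlets(model, n_dbl)
    out[prov == "doublet", ] <- data.frame(
      FSC_A = a$FSC_A + b$FSC_A,
      FSC_W = a$FSC_W * stats::runif(n_dbl, 1.6, 2.2),
      SSC_A = a$SSC_A + b$SSC_A,
      GFP = a$GFP + b$GFP,
      mCherry = a$mCherry + b$mCherry)
  }
  out <- cbind(event_id = seq_len(n_cells), out, provenance = prov)
  new_event_table(out)
}

#' F1 cross design
#'
#' Describes a cross between an evolved clone and its ancestor: one causal
#' locus whose evolved allele shifts the noise phenotype (Fano factor) plus
#' neutral loci, positioned on a genetic map.
#'
#' @param n_loci Number of loci.
#' @param causal_index Index (1-based) of the causal locus.
#' @param map_positions Data.frame with columns `chrom` and `cM`, one row per
#'   locus. Defaults to every locus on its own chromosome (all unlinked).
#' @param n_segregants Number of F1 haploid segregants.
#' @param base_fano Ancestral-allele Fano level of the phenotype.
#' @param phenotype_effect Fano shift conferred by the causal evolved allele.
#' @param phenotype_noise_sd SD of replicate measurement noise.
#' @param n_replicates Phenotype replicates per segregant.
#' @return An object of class `cross_design`.
#' @export
cross_design <- function(n_loci = 50, causal_index = 25,
                         map_positions = NULL,
                         n_segregants = 100,
                         base_fano = 1.0, phenotype_effect = 1.0,
                         phenotype_noise_sd = 0.05, n_replicates = 3) {
  if (is.null(map_positions))
    map_positions <- data.frame(chrom = paste0("chr", seq_len(n_loci)),
                                cM = rep(0, n_loci))
  stopifnot(nrow(map_positions) == n_loci,
            all(c("chrom", "cM") %in% names(map_positions)),
            causal_index >= 1, causal_index <= n_loci,
            n_replicates >= 1, n_segregants >= 1,
            phenotype_noise_sd >= 0)
  structure(list(n_loci = n_loci, causal_index = causal_index,
                 map_positions = map_positions,
                 n_segregants = n_segregants,
                 base_fano = base_fano,
                 phenotype_effect = phenotype_effect,
                 phenotype_noise_sd = phenotype_noise_sd,
                 n_replicates = n_replicates),
            class = "cross_design")
}

#' Haldane recombination fraction
#'
#' Map distance d (centimorgan) to recombination probability under the
#' Haldane (no-interference) map function, r = (1 - exp(-2d/100)) / 2.
#'
#' @param d_cM Map distance in centimorgan (>= 0).
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Simulate F1 segregants from a cross
#'
#' Each segregant inherits the evolved allele at the leftmost locus of each
#' chromosome with probability 1/2; adjacent loci on the same chromosome
#' recombine with the Haldane probability for their map distance; loci on
#' different chromosomes assort independently. Each segregant receives
#' `n_replicates` phenotype draws: base Fano plus the causal effect if it
#' carries the evolved causal allele, plus Gaussian measurement noise.
#'
#' @param design A [cross_design()].
#' @param seed Integer seed.
#' @return List with `genotypes` (n_segregants x n_loci matrix, 1 = evolved
#'   allele), `phenotypes` (n_segregants x n_replicates matrix of Fano
#'   values), and the `design`.
#' @export
gen_segregants <- function(design, seed) {
  stopifnot(inherits(design, "cross_design"))
  set.seed(as.integer(seed))
  map <- design$map_positions
  n <- design$n_segregants
  L <- design$n_loci
  geno <- matrix(0L, n, L)
  chroms <- unique(map$chrom)
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    idx <- idx[order(map$cM[idx])]
    geno[, idx[1]] <- stats::rbinom(n, 1L, 0.5)
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        r <- haldane_r(map$cM[idx[k]] - map$cM[idx[k - 1]])
        flip <- stats::rbinom(n, 1L, r)
        geno[, idx[k]] <- ifelse(flip == 1L,
                                 1L - geno[, idx[k - 1]],
                                 geno[, idx[k - 1]])
      }
    }
  }
  causal <- geno[, design$causal_index]
  pheno <- matrix(design$base_fano + design$phenotype_effect * causal,
                  n, design$n_replicates) +
    matrix(stats::rnorm(n * design$n_replicates, 0, design$phenotype_noise_sd),
           n, design$n_replicates)
  list(genotypes = geno, phenotypes = pheno, design = design)
}

#' Simulate pooled sequencing read counts for one bulk
#'
#' Per site, the true alternate (evolved-parent) allele frequency is the
#' fraction of pooled segregants carrying the evolved allele; the observed
#' alternate count is Binomial(depth, p(1-e) + (1-p)e) with symmetric base
#' error rate e.
#'
#' @param pool_genotypes Matrix (pool members x loci) of 0/1 genotypes.
#' @param depth Reads per site (>= 1).
#' @param error_rate Symmetric per-read error probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return Data.frame with columns locus, p_true, depth, alt_count,
#'   ref_count.
#' @export
gen_pool_reads <- function(pool_genotypes, depth, error_rate = 0, seed = 1) {
  if (is.null(dim(pool_genotypes)) || nrow(pool_genotypes) < 1)
    stop("empty pool")
  stopifnot(depth >= 1, error_rate >= 0, error_rate < 0.5)
  set.seed(as.integer(seed))
  p <- colMeans(pool_genotypes)
  p_obs <- p * (1 - error_rate) + (1 - p) * error_rate
  alt <- stats::rbinom(length(p), depth, p_obs)
  data.frame(locus = seq_along(p), p_true = p, depth = depth,
             alt_count = alt, ref_count = depth - alt)
}

#' Combine per-bulk pool reads into a two-bulk count table
#'
#' @param evolved,ancestral Outputs of [gen_pool_reads()] on the evolved-like
#'   and ancestral-like pools (same loci).
#' @param map_positions Optional data.frame (`chrom`, `cM`) giving site
#'   coordinates; positions are emitted 1-based.
#' @return Data.frame in the bulk-count schema: chrom, pos, ref, alt,
#'   ref_count_evolved, alt_count_evolved, ref_count_ancestral,
#'   alt_count_ancestral.
#' @export
pool_counts_table <- function(evolved, ancestral, map_positions = NULL) {
  stopifnot(nrow(evolved) == nrow(ancestral))
  L <- nrow(evolved)
  if (is.null(map_positions))
    map_positions <- data.frame(chrom = paste0("chr", seq_len(L)),
                                cM = rep(0, L))
  data.frame(chrom = map_positions$chrom,
             pos = as.integer(round(map_positions$cM * 1000)) + 1L,
             ref = "A", alt = "T",
             ref_count_evolved = evolved$ref_count,
             alt_count_evolved = evolved$alt_count,
             ref_count_ancestral = ancestral$ref_count,
             alt_count_ancestral = ancestral$alt_count,
             stringsAsFactors = FALSE)
}

#' Generate a logistic growth curve with measurement noise
#'
#' OD(t) = capacity / (1 + exp(-rate * (t - t_mid))) with t_mid placed so
#' growth starts near `od0` after the lag; additive Gaussian noise. The
#' analytic maximum slope rate*capacity/4 occurs at half capacity.
#'
#' @param rate Intrinsic rate (per min, > 0).
#' @param lag Lag time before exponential phase (min).
#' @param capacity Carrying capacity (OD units, > 0).
#' @param dt Sampling interval (min); the plate-reader default is 12.
#' @param noise_sd SD of additive OD noise.
#' @param seed Integer seed.
#' @param n_points Number of time points.
#' @param od0 Initial OD.
#' @return Data.frame (time, od) with attributes `rate`, `capacity`,
#'   `t_mid`, and `max_slope` (= rate * capacity / 4) as ground truth.
#' @export
gen_growth_curve <- function(rate, lag = 0, capacity = 1, dt = 12,
                             noise_sd = 0, seed = 1, n_points = 100,
                             od0 = 0.01) {
  stopifnot(rate > 0, capacity > od0, od0 > 0, dt > 0, noise_sd >= 0)
  set.seed(as.integer(seed))
  t <- seq(0, by = dt, length.out = n_points)
  t_mid <- lag + log(capacity / od0 - 1) / rate
  od <- capacity / (1 + exp(-rate * (t - t_mid))) +
    stats::rnorm(n_points, 0, noise_sd)
  structure(data.frame(time = t, od = od),
            rate = rate, capacity = capacity, t_mid = t_mid,
            max_slope = rate * capacity / 4)
}

#' Generate a polysome A254 trace as a sum of Gaussian peaks
#'
#' @param peak_centers,peak_areas,widths Equal-length vectors of peak
#'   centers (gradient coordinate), areas, and Gaussian SDs.
#' @param baseline Flat baseline absorbance (>= 0).
#' @param noise_sd SD of additive absorbance noise.
#' @param seed Integer seed.
#' @param n_points Number of trace samples.
#' @param xlim Position range; defaults to cover all peaks +/- 5 widths.
#' @return Data.frame (position, a254) with attributes `peak_centers`,
#'   `peak_areas`, `widths`, `baseline`, and `boundaries` (center +/- 4
#'   widths per peak) as ground truth.
#' @export
gen_polysome_trace <- function(peak_centers, peak_areas, widths,
                               baseline = 0, noise_sd = 0, seed = 1,
                               n_points = 2000, xlim = NULL) {
  stopifnot(length(peak_centers) == length(peak_areas),
            length(peak_centers) == length(widths),
            all(peak_areas > 0), all(widths > 0))
  if (baseline < 0) stop("negative baseline rejected")
  set.seed(as.integer(seed))
  if (is.null(xlim))
    xlim <- c(min(peak_centers - 5 * widths), max(peak_centers + 5 * widths))
  x <- seq(xlim[1], xlim[2], length.out = n_points)
  y <- rep(baseline, n_points)
  for (i in seq_along(peak_centers))
    y <- y + peak_areas[i] * stats::dnorm(x, peak_centers[i], widths[i])
  y <- y + stats::rnorm(n_points, 0, noise_sd)
  structure(data.frame(position = x, a254 = y),
            peak_centers = peak_centers, peak_areas = peak_areas,
            widths = widths, baseline = baseline,
            boundaries = data.frame(start = peak_centers - 4 * widths,
                                    end = peak_centers + 4 * widths))
}
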