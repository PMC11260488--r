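#' @section Evolution simulator:
#' Stochastic simulator of the noise-enrichment selection protocol: a single
#' round of chemical (EMS) mutagenesis seeds mutant lineages, then the
#' population alternates FACS sorts of the 10% outermost cells in the
#' two-reporter plane (first in the off-diagonal quadrants QII and QIV,
#' then in the high/high quadrant QI) with recovery growth in glycerol
#' medium. The quadrant alternation counter-selects general
#' activators/repressors (which move along the diagonal) and broken
#' reporters (which cannot reach QI); glycerol recovery counter-selects
#' respiration-deficient (mito-defect) lineages. Lineages are parameter
#' vectors, not genomes; recovery is deterministic exponential growth
#' followed by multinomial resampling.
#' @name evolution_sim
#' @keywords internal
NULL

NV_LINEAGE_CLASSES <- c("wild_type", "noise_up", "general_regulator",
                        "gfp_defect", "mcherry_defect", "mito_defect",
                        "neutral")

#' Found a population of one wild-type lineage
#'
#' @param n_cells Founding abundance.
#' @param base_model [reporter_model()] of the wild type; also supplies
#'   scatter and contamination parameters for every derived lineage.
#' @return A `population` object (list of `lineages` data.frame and the
#'   base model).
#' @export
founding_population <- function(n_cells = 1e6, base_model = reporter_model()) {
  lineages <- data.frame(
    id = "wt", class = "wild_type",
    mu_gfp = base_model$mu_gfp, mu_mcherry = base_model$mu_mcherry,
    sigma_int_gfp = base_model$sigma_int_gfp,
    sigma_int_mcherry = base_model$sigma_int_mcherry,
    sigma_ext = base_model$sigma_ext,
    growth_rate = 1, gfp_defect = FALSE, mcherry_defect = FALSE,
    mito_defect = FALSE, abundance = as.numeric(n_cells),
    stringsAsFactors = FALSE)
  structure(list(lineages = lineages, base = base_model),
            class = "population")
}

#' Add a lineage with explicit parameters
#'
#' Convenience for constructing test populations without mutagenesis.
#'
#' @param population A `population`.
#' @param class Lineage class label.
#' @param abundance Cell count.
#' @param sigma_multiplier Multiplier on all noise sigmas (intrinsic and
#'   extrinsic) relative to wild type.
#' @param mean_multiplier Multiplier on both channel means.
#' @param gfp_defect,mcherry_defect,mito_defect Defect flags; reporter
#'   defects drop the channel mean to 2% of wild type (autofluorescence
#'   background), a mito defect caps glycerol growth at 0.05x wild type.
#' @param id Lineage id (defaults to class plus counter).
#' @return The updated `population`.
#' @export
add_lineage <- function(population, class, abundance,
                        sigma_multiplier = 1, mean_multiplier = 1,
                        gfp_defect = FALSE, mcherry_defect = FALSE,
                        mito_defect = FALSE, id = NULL) {
  base <- population$base
  if (is.null(id))
    id <- paste0(class, "_", nrow(population$lineages) + 1)
  row <- data.frame(
    id = id, class = class,
    mu_gfp = base$mu_gfp * mean_multiplier *
      (if (gfp_defect) 0.02 else 1),
    mu_mcherry = base$mu_mcherry * mean_multiplier *
      (if (mcherry_defect) 0.02 else 1),
    sigma_int_gfp = base$sigma_int_gfp * sigma_multiplier,
    sigma_int_mcherry = base$sigma_int_mcherry * sigma_multiplier,
    sigma_ext = base$sigma_ext * sigma_multiplier,
    growth_rate = if (mito_defect) 0.05 else 1,
    gfp_defect = gfp_defect, mcherry_defect = mcherry_defect,
    mito_defect = mito_defect, abundance = as.numeric(abundance),
    stringsAsFactors = FALSE)
  population$lineages <- rbind(population$lineages, row)
  population
}

#' Per-class lineage frequencies
#'
#' @param population A `population`.
#' @return Named numeric vector of class frequencies (summing to 1).
#' @export
lineage_frequencies <- function(population) {
  ab <- population$lineages$abundance
  tapply(ab / sum(ab), population$lineages$class, sum)
}

#' One-shot EMS mutagenesis
#'
#' A fraction of cells acquire mutations and found new lineages; each mutant
#' cell is assigned an effect class by the given probabilities (classes:
#' noise_up, general_regulator, gfp_defect, mcherry_defect, mito_defect,
#' neutral). Mutagenesis is applied once, before any sorting. Per class up
#' to `lineages_per_class` distinct lineages are founded (splitting the
#' class's cells), each with an independently drawn effect size: noise-up
#' lineages multiply all sigmas by Uniform(1.5, 2.5); general regulators
#' multiply both channel means by a factor in [2, 4], up or down with equal
#' probability.
#'
#' @param population A `population` of one founding wild-type lineage.
#' @param mutant_fraction Fraction of cells mutagenized.
#' @param class_probs Named numeric vector of class probabilities summing to
#'   at most 1 (remainder stays wild type).
#' @param seed Integer seed.
#' @param lineages_per_class Cap on founded lineages per class.
#' @return The mutagenized `population`.
#' @export
ems_mutagenize <- function(population, mutant_fraction = 1,
                           class_probs = c(noise_up = 1e-3,
                                           general_regulator = 1e-3,
                                           gfp_defect = 5e-4,
                                           mcherry_defect = 5e-4,
                                           mito_defect = 1e-3,
                                           neutral = 0.996),
                           seed = 1, lineages_per_class = 3) {
  if (nrow(population$lineages) != 1 ||
      population$lineages$class != "wild_type")
    stop("mutagenesis expects a single founding wild-type lineage")
  stopifnot(mutant_fraction >= 0, mutant_fraction <= 1,
            all(class_probs >= 0))
  if (sum(class_probs) > 1 + 1e-12)
    stop("class probabilities must sum to at most 1")
  bad <- setdiff(names(class_probs), NV_LINEAGE_CLASSES)
  if (length(bad)) stop("unknown lineage class(es): ",
                        paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  N <- population$lineages$abundance[1]
  n_mut <- stats::rbinom(1, round(N), mutant_fraction)
  p <- c(class_probs, wild_type = max(0, 1 - sum(class_probs)))
  counts <- as.vector(stats::rmultinom(1, n_mut, p))
  names(counts) <- names(p)
  counts["wild_type"] <- counts["wild_type"] + (round(N) - n_mut)
  pop <- population
  pop$lineages$abundance[1] <- counts["wild_type"]
  for (cls in setdiff(names(counts), "wild_type")) {
    k <- counts[[cls]]
    if (k == 0) next
    n_lin <- min(lineages_per_class, k)
    split <- rep(floor(k / n_lin), n_lin)
    split[1] <- split[1] + k - sum(split)
    for (j in seq_len(n_lin)) {
      args <- list(population = pop, class = cls, abundance = split[j])
      if (cls == "noise_up")
        args$sigma_multiplier <- stats::runif(1, 1.5, 2.5)
      if (cls == "general_regulator") {
        f <- exp(stats::runif(1, log(2), log(4)))
        args$mean_multiplier <- if (stats::runif(1) < 0.5) f else 1 / f
      }
      if (cls == "gfp_defect") args$gfp_defect <- TRUE
      if (cls == "mcherry_defect") args$mcherry_defect <- TRUE
      if (cls == "mito_defect") args$mito_defect <- TRUE
      pop <- do.call(add_lineage, args)
    }
  }
  pop
}

lineage_model <- function(lineage, base) {
  reporter_model(mu_gfp = lineage$mu_gfp, mu_mcherry = lineage$mu_mcherry,
                 sigma_ext = lineage$sigma_ext,
                 sigma_int_gfp = lineage$sigma_int_gfp,
                 sigma_int_mcherry = lineage$sigma_int_mcherry,
                 scatter_mu = base$scatter_mu,
                 scatter_sigma = base$scatter_sigma,
                 rho_scatter = base$rho_scatter,
                 f_debris = base$f_debris, f_doublet = base$f_doublet)
}

#' Draw a cytometry sample from a lineage mixture
#'
#' Cells are assigned to lineages multinomially by abundance; each cell's
#' channels come from its lineage's reporter model. Rows are shuffled so
#' event index carries no lineage information.
#'
#' @param population A `population`.
#' @param n_sample Number of events.
#' @param seed Integer seed.
#' @return An `event_table` with a `lineage` id column.
#' @export
sample_events_from_population <- function(population, n_sample, seed) {
  lin <- population$lineages
  lin <- lin[lin$abundance > 0, , drop = FALSE]
  if (nrow(lin) == 0 || sum(lin$abundance) <= 0)
    stop("population is empty")
  set.seed(as.integer(seed))
  counts <- as.vector(stats::rmultinom(1, n_sample,
                                       lin$abundance / sum(lin$abundance)))
  parts <- vector("list", nrow(lin))
  for (i in seq_len(nrow(lin))) {
    if (counts[i] == 0) next
    ev <- gen_events(lineage_model(lin[i, ], population$base), counts[i],
                     seed = derive_seed(seed, i))
    ev$lineage <- lin$id[i]
    parts[[i]] <- as.data.frame(ev)
  }
  out <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  set.seed(derive_seed(seed, 0))
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  out$event_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  new_event_table(out)
}

#' Select the outermost cells of the two-reporter distribution
#'
#' Ranks gated, log-transformed events by Mahalanobis distance from the
#' population centroid in the (log GFP, log mCherry) plane using the sample
#' covariance, and selects exactly `floor(fraction * n)` events with the
#' largest distances; ties are broken by event index. This is the in-silico
#' analogue of collecting the cells outside an elliptical sort region
#' covering 90% of the population. If the covariance is singular (e.g. a
#' constant channel) the ranking falls back to Euclidean distance with a
#' warning.
#'
#' @param events A gated `event_table` with log GFP/mCherry (n >= 10).
#' @param fraction Fraction of cells to select (default 0.10).
#' @return Logical mask over the events, `sum(mask) == floor(fraction * n)`.
#' @export
outermost_selection <- function(events, fraction = 0.10) {
  require_channels(events, c("GFP", "mCherry"))
  n <- nrow(events)
  if (n < 10) stop("need at least 10 events")
  if (!all(c("GFP", "mCherry") %in% attr(events, "log_channels")))
    stop("events must be log-transformed (run gate_pipeline first)")
  X <- cbind(events$GFP, events$mCherry)
  S <- stats::cov(X)
  evs <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(evs) <= 1e-12 * max(max(evs), 1e-300)) {
    warning("singular covariance; falling back to Euclidean distance")
    ctr <- colMeans(X)
    d <- (X[, 1] - ctr[1])^2 + (X[, 2] - ctr[2])^2
  } else {
    d <- stats::mahalanobis(X, colMeans(X), S)
  }
  k <- floor(fraction * n)
  sel <- order(-d, seq_len(n))[seq_len(k)]
  mask <- rep(FALSE, n)
  mask[sel] <- TRUE
  mask
}

#' Quadrant masks in the two-reporter plane
#'
#' Quadrant boundaries are the per-channel medians of the gated population.
#' QI holds cells above both medians; QII high mCherry / at-or-below-median
#' GFP; QIV high GFP / at-or-below-median mCherry. Events exactly at a
#' median fall on the "at/below" side.
#'
#' @param events A gated, log-transformed `event_table`.
#' @param which One of "QI", "QII", "QIV".
#' @return Logical mask over the events.
#' @export
quadrant_mask <- function(events, which = c("QI", "QII", "QIV")) {
  which <- match.arg(which)
  require_channels(events, c("GFP", "mCherry"))
  mg <- stats::median(events$GFP)
  mm <- stats::median(events$mCherry)
  switch(which,
         QI  = events$GFP > mg & events$mCherry > mm,
         QII = events$mCherry > mm & events$GFP <= mg,
         QIV = events$GFP > mg & events$mCherry <= mm)
}

#' One FACS sort step
#'
#' Draws a cytometry sample from the lineage mixture, runs the gating
#' pipeline, intersects the outermost-cell mask with the requested quadrant
#' gate (QII and QIV are pooled into one tube in the first sort of each
#' round), and keeps up to `n_sorted` selected cells. The new population
#' abundances are the per-lineage counts among sorted cells.
#'
#' @param population A `population`.
#' @param gate "QII_QIV" or "QI".
#' @param fraction Outermost fraction (default 0.10).
#' @param n_sorted Cap on sorted cells.
#' @param n_sample Events drawn for the sort (simulator scale; the bench
#'   protocol sorts from a much larger stream).
#' @param seed Integer seed.
#' @return The post-sort `population`, with attribute `sort_stats` (gated
#'   sample Fano per channel and per-class frequencies before/after).
#' @export
sort_step <- function(population, gate = c("QII_QIV", "QI"),
                      fraction = 0.10, n_sorted = 1e5, n_sample = 1e4,
                      seed = 1) {
  gate <- match.arg(gate)
  ev <- sample_events_from_population(population, n_sample, seed)
  gated <- gate_pipeline(ev)
  outer <- outermost_selection(gated, fraction)
  quad <- if (gate == "QI") quadrant_mask(gated, "QI")
          else quadrant_mask(gated, "QII") | quadrant_mask(gated, "QIV")
  sel <- outer & quad
  if (!any(sel)) stop("selection extinguished population")
  idx <- which(sel)
  if (length(idx) > n_sorted) idx <- idx[seq_len(n_sorted)]
  picked <- table(gated$lineage[idx])
  lin <- population$lineages
  lin$abundance <- as.numeric(picked[lin$id])
  lin$abundance[is.na(lin$abundance)] <- 0
  out <- population
  out$lineages <- lin
  attr(out, "sort_stats") <- list(
    gate = gate,
    n_gated = nrow(gated), n_sorted = length(idx),
    fano_gfp = fano(gated$GFP)$fano,
    fano_mcherry = fano(gated$mCherry)$fano,
    freq_before = lineage_frequencies(population),
    freq_after = lineage_frequencies(out))
  out
}

#' Recovery growth in glycerol medium
#'
#' Deterministic exponential growth for a fixed number of wild-type
#' generations followed by multinomial resampling to the target population
#' size. Lineage weights are abundance times 2^(growth_rate * generations);
#' mito-defective lineages (growth 0.05x) are strongly depleted because
#' glycerol is non-fermentable.
#'
#' @param population A `population`.
#' @param target_size Post-recovery population size.
#' @param generations Wild-type doublings during recovery (default 10).
#' @param seed Integer seed.
#' @return The recovered `population`; total abundance equals `target_size`
#'   exactly.
#' @export
recover_population <- function(population, target_size, generations = 10,
                               seed = 1) {
  lin <- population$lineages
  if (sum(lin$abundance) <= 0) stop("population is empty")
  set.seed(as.integer(seed))
  w <- lin$abundance * 2^(lin$growth_rate * generations)
  counts <- as.vector(stats::rmultinom(1, target_size, w / sum(w)))
  out <- population
  out$lineages$abundance <- as.numeric(counts)
  out
}

#' Run the full selection protocol
#'
#' EMS mutagenesis once, then `n_rounds` of
#' sort(QII u QIV) -> recover -> sort(QI) -> recover. The trajectory records
#' per-step lineage-class frequencies and the gated-sample Fano of both
#' channels.
#'
#' @param config An [evolution_config()] list.
#' @param n_rounds Selection rounds (default 2).
#' @param seed Run-level integer seed; stage seeds derive from it by fixed
#'   offsets.
#' @return List with `population` (final) and `trajectory` (data.frame:
#'   step, step_type, lineage_class, frequency, fano_gfp, fano_mcherry).
#' @export
run_protocol <- function(config = evolution_config(), n_rounds = 2,
                         seed = 1) {
  pop <- founding_population(config$n_founding, config$base_model)
  pop <- ems_mutagenize(pop, config$mutant_fraction, config$class_probs,
                        seed = derive_seed(seed, 101),
                        lineages_per_class = config$lineages_per_class)
  traj <- list()
  record <- function(step, type, pop, fg, fm) {
    fr <- lineage_frequencies(pop)
    data.frame(step = step, step_type = type,
               lineage_class = names(fr), frequency = as.numeric(fr),
               fano_gfp = fg, fano_mcherry = fm,
               stringsAsFactors = FALSE)
  }
  measure <- function(pop, seed) {
    ev <- gate_pipeline(
      sample_events_from_population(pop, config$n_sample, seed))
    c(fano(ev$GFP)$fano, fano(ev$mCherry)$fano)
  }
  f0 <- measure(pop, derive_seed(seed, 102))
  traj[[1]] <- record("initial", "init", pop, f0[1], f0[2])
  step_i <- 0
  for (round in seq_len(n_rounds)) {
    for (gate in c("QII_QIV", "QI")) {
      step_i <- step_i + 1
      pop <- sort_step(pop, gate, fraction = config$outer_fraction,
                       n_sorted = config$n_sorted,
                       n_sample = config$n_sample,
                       seed = derive_seed(seed, 200 + step_i))
      st <- attr(pop, "sort_stats")
      traj[[length(traj) + 1]] <- record(
        sprintf("round%d_sort_%s", round, gate), "sort", pop,
        st$fano_gfp, st$fano_mcherry)
      step_i <- step_i + 1
      pop <- recover_population(pop, config$target_size,
                                generations = config$generations,
                                seed = derive_seed(seed, 200 + step_i))
      traj[[length(traj) + 1]] <- record(
        sprintf("round%d_recover_after_%s", round, gate), "recover", pop,
        NA_real_, NA_real_)
    }
  }
  list(population = pop, trajectory = do.call(rbind, traj))
}
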