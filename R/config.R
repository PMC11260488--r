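#' Derive a stage seed from a run-level seed
#'
#' Every stochastic stage receives a seed derived from the run-level seed by
#' a fixed stage offset, so a single integer reproduces a whole run while
#' stages stay decorrelated. The derivation keeps seeds within the 32-bit
#' integer range.
#'
#' @param seed Run-level integer seed.
#' @param offset Fixed stage offset.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset)) %% 2147483647)
}

#' Default configuration of the selection-protocol simulator
#'
#' Simulator scale defaults to 1e4 events per sort sample (the bench
#' protocol sorts 1e5 cells from a much larger stream; the frequency
#' dynamics are scale-free, so desk scale preserves the behaviour being
#' studied).
#'
#' @param n_founding Founding population size before mutagenesis.
#' @param mutant_fraction Fraction of cells mutagenized by EMS.
#' @param class_probs Mutation-class probabilities (see [ems_mutagenize()]).
#' @param base_model Wild-type [reporter_model()].
#' @param n_sample Events per cytometry sample.
#' @param n_sorted Cap on cells kept per sort.
#' @param outer_fraction Outermost fraction collected per sort.
#' @param target_size Post-recovery population size.
#' @param generations Wild-type doublings per recovery.
#' @param lineages_per_class Cap on lineages founded per mutation class.
#' @return A named list consumed by [run_protocol()].
#' @export
evolution_config <- function(n_founding = 1e6,
                             mutant_fraction = 1,
                             class_probs = c(noise_up = 1e-3,
                                             general_regulator = 1e-3,
                                             gfp_defect = 5e-4,
                                             mcherry_defect = 5e-4,
                                             mito_defect = 1e-3,
                                             neutral = 0.996),
                             base_model = reporter_model(),
                             n_sample = 1e4, n_sorted = 1e5,
                             outer_fraction = 0.10,
                             target_size = 1e5, generations = 10,
                             lineages_per_class = 3) {
  list(n_founding = n_founding, mutant_fraction = mutant_fraction,
       class_probs = class_probs, base_model = base_model,
       n_sample = n_sample, n_sorted = n_sorted,
       outer_fraction = outer_fraction, target_size = target_size,
       generations = generations, lineages_per_class = lineages_per_class)
}

#' Run-level configuration
#'
#' Bundles the stage parameter sets with a run-level seed; each stochastic
#' stage receives `derive_seed(seed, offset)` with a fixed per-stage offset.
#' Round-trips losslessly through JSON.
#'
#' @param seed Run-level integer seed.
#' @param gating List of gating parameters (min_fsc, width_quantile,
#'   fraction, bins, log_base).
#' @param evolution [evolution_config()] list.
#' @param cross [cross_design()] parameters as a list.
#' @param bsa List of SNP-index filter thresholds.
#' @return An `nv_config` list.
#' @export
nv_config <- function(seed = 1,
                      gating = list(min_fsc = 2570, width_quantile = 0.90,
                                    fraction = 0.80, bins = 64,
                                    log_base = 10),
                      evolution = evolution_config(),
                      cross = list(n_loci = 50, causal_index = 25,
                                   n_segregants = 100, pool_size = 20,
                                   depth = 200, error_rate = 0),
                      bsa = list(min_index = 0.3, causal_threshold = 0.8,
                                 min_coverage = 30, min_af = 0.5)) {
  structure(list(seed = seed, gating = gating, evolution = evolution,
                 cross = cross, bsa = bsa),
            class = "nv_config")
}
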