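#' Demographic/selection configuration for the haplotype simulator
#'
#' Bundles every parameter of one simulation scenario. Defaults are the
#' two-breed cattle resequencing design the package's calibration study
#' emulates: theta = 0.0012 per site, Ne = 300 diploids, 5-year generations,
#' 20 + 22 sampled chromosomes, a split 1,200 generations ago, 100 segregating
#' sites conditioned per replicate and a 1-Mb region.
#'
#' @param theta scaled mutation parameter 4*Ne*mu per site; used only when
#'   `fixed_s` is `NULL`.
#' @param n_e effective diploid population size.
#' @param gen_years years per generation (for converting ka to generations).
#' @param n_hap_a,n_hap_b sampled chromosome counts for populations A and B.
#' @param split_gen divergence time of A and B, in generations before present.
#' @param fixed_s condition every replicate on exactly this many segregating
#'   sites (`NULL` = mutations Poisson with rate theta).
#' @param region_bp simulated region length in bp.
#' @param bottleneck `NULL`, or `list(start_gen=, end_gen=, intensity=)`:
#'   population size multiplied by `intensity` between the two times
#'   (generations ago; `start_gen` is the older bound). Intervals older than
#'   `split_gen` act on the ancestral lineage.
#' @param selection `NULL`, or `list(alpha=, onset_gen=)`: a sweep in
#'   population A at a core site, scaled selection strength `alpha = 2*Ne*s`
#'   starting `onset_gen` generations before present, with additive fitness
#'   1, 1+s, 1+2s for 0/1/2 copies of the favoured allele.
#' @param recomb_rate per-bp per-generation crossover rate for the forward
#'   sweep phase (default 1e-8, i.e. 1 cM/Mb). The neutral coalescent is run
#'   without intra-locus recombination, matching fixed-S usage.
#' @param seed optional RNG seed applied by the `simulate_*` functions.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config()
#' cfg$n_hap_a + cfg$n_hap_b
#' @export
sim_config <- function(theta = 0.0012, n_e = 300, gen_years = 5,
                       n_hap_a = 20, n_hap_b = 22, split_gen = 1200,
                       fixed_s = 100, region_bp = 1e6, bottleneck = NULL,
                       selection = NULL, recomb_rate = 1e-8, seed = NULL) {
  if (n_hap_a + n_hap_b <= 0) stop("n_hap_a + n_hap_b must be positive")
  if (split_gen <= 0) stop("split_gen must be > 0")
  if (!is.null(fixed_s) && fixed_s < 1) stop("fixed_s must be >= 1 when set")
  if (!is.null(bottleneck)) {
    b <- bottleneck
    if (!all(c("start_gen", "end_gen", "intensity") %in% names(b)))
      stop("bottleneck needs start_gen, end_gen, intensity")
    if (b$start_gen <= b$end_gen)
      stop("bottleneck start_gen must be older (larger) than end_gen; ",
           "times are generations ago")
    if (b$intensity <= 0 || b$intensity > 1)
      stop("bottleneck intensity must be in (0, 1]")
  }
  if (!is.null(selection)) {
    if (!all(c("alpha", "onset_gen") %in% names(selection)))
      stop("selection needs alpha and onset_gen")
    if (selection$onset_gen < 1) stop("selection onset_gen must be >= 1")
    if (selection$alpha < 0) stop("selection alpha must be >= 0")
  }
  structure(list(theta = theta, n_e = n_e, gen_years = gen_years,
                 n_hap_a = as.integer(n_hap_a), n_hap_b = as.integer(n_hap_b),
                 split_gen = split_gen, fixed_s = fixed_s,
                 region_bp = region_bp, bottleneck = bottleneck,
                 selection = selection, recomb_rate = recomb_rate,
                 seed = seed),
            class = "sim_config")
}

#' The four calibration scenarios
#'
#' Convenience constructor for the neutral, bottleneck, weak-sweep and
#' strong-sweep configurations of the calibration study: the neutral model
#' plus (i) a size reduction to 1% of Ne between 8,000 and 7,200 generations
#' ago (40--36 ka at 5 y/gen) and (ii) sweeps of scaled strength 100 or 500
#' starting 10 generations before present.
#'
#' @param ... overrides forwarded to [sim_config()] for all four scenarios.
#' @return Named list of `sim_config` objects: `neutral`, `bottleneck`,
#'   `weak_sweep`, `strong_sweep`.
#' @export
default_scenarios <- function(...) {
  base <- sim_config(...)
  bn <- list(start_gen = 40000 / base$gen_years,
             end_gen = 36000 / base$gen_years, intensity = 0.01)
  list(
    neutral = base,
    bottleneck = sim_config(..., bottleneck = bn),
    weak_sweep = sim_config(..., selection = list(alpha = 100,
                                                  onset_gen = 10)),
    strong_sweep = sim_config(..., selection = list(alpha = 500,
                                                    onset_gen = 10)))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d+%d haplotypes, split %g gen, Ne=%g, theta=%g/site, %s\n",
    x$n_hap_a, x$n_hap_b, x$split_gen, x$n_e, x$theta,
    if (!is.null(x$fixed_s)) sprintf("S=%d fixed", as.integer(x$fixed_s))
    else sprintf("%g bp region", x$region_bp)))
  if (!is.null(x$bottleneck))
    cat(sprintf("  bottleneck: x%g from %g to %g gen ago\n",
                x$bottleneck$intensity, x$bottleneck$start_gen,
                x$bottleneck$end_gen))
  if (!is.null(x$selection))
    cat(sprintf("  selection in A: alpha=%g (s=%g), onset %g gen ago\n",
                x$selection$alpha, x$selection$alpha / (2 * x$n_e),
                x$selection$onset_gen))
  invisible(x)
}
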