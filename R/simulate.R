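#' Simulate two neutrally diverged populations
#'
#' Hudson-style coalescent for two demes that merge (backward in time) at
#' `split_gen` generations ago, with mutations either conditioned to exactly
#' `fixed_s` segregating sites (placed on branches with probability
#' proportional to branch length) or Poisson with per-site rate `theta`.
#' Site positions are distinct uniform integers over `region_bp`, sorted.
#' Rows are ordered population A then B.
#'
#' @param config a [sim_config()] without selection.
#' @return A [haplotype_matrix()] with `config$n_hap_a + config$n_hap_b` rows.
#' @examples
#' m <- simulate_neutral(sim_config(seed = 1))
#' dim(m$alleles)
#' @export
simulate_neutral <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$selection))
    stop("config has selection set; use simulate_sweep()")
  if (!is.null(config$seed)) set.seed(config$seed)
  br <- .coalescent_branches(config)
  .matrix_from_sim(.place_mutations(br, config), config)
}

#' Simulate a bottlenecked history
#'
#' As [simulate_neutral()], with the population size multiplied by
#' `bottleneck$intensity` between `start_gen` and `end_gen` generations ago.
#' An interval older than the split acts on the ancestral lineage (the
#' default calibration bottleneck, 8,000--7,200 generations ago at intensity
#' 0.01, is of this kind).
#'
#' @param config a [sim_config()] with `bottleneck` set.
#' @return A [haplotype_matrix()].
#' @export
simulate_bottleneck <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$bottleneck))
    stop("config has no bottleneck; use simulate_neutral()")
  if (!is.null(config$selection))
    stop("config has selection set; use simulate_sweep()")
  if (!is.null(config$seed)) set.seed(config$seed)
  br <- .coalescent_branches(config)
  .matrix_from_sim(.place_mutations(br, config), config)
}

#' Deterministic sweep allele-frequency recursion
#'
#' Discrete-generation expectation of the favoured-allele frequency under
#' additive viability selection (fitness 1, 1+s, 1+2s), the infinite-
#' population limit of the forward Wright-Fisher phase:
#' `p' = p (1 + s + s p) / (1 + 2 s p)`.
#'
#' @param p0 starting frequency in (0, 1).
#' @param s selection coefficient per copy.
#' @param n_gen number of generations.
#' @return Numeric vector of length `n_gen + 1`: the trajectory including
#'   `p0`.
#' @export
deterministic_sweep_trajectory <- function(p0, s, n_gen) {
  stopifnot(p0 > 0, p0 < 1, n_gen >= 0)
  p <- numeric(n_gen + 1L)
  p[1L] <- p0
  for (g in seq_len(n_gen))
    p[g + 1L] <- p[g] * (1 + s + s * p[g]) / (1 + 2 * s * p[g])
  p
}

# One forward Wright-Fisher generation pass over phased haplotypes.
# haps: 2N x m matrix, individual i = rows (2i-1, 2i). Selection acts on the
# derived allele at column `core`; gametes recombine with Poisson crossovers.
# Returns NULL if the favoured allele is lost.
.forward_sweep <- function(haps, core, s, n_gen, recomb_rate, region_bp,
                           positions) {
  n_dip <- nrow(haps) %/% 2L
  m <- ncol(haps)
  odd <- seq(1L, 2L * n_dip, 2L)
  lambda <- recomb_rate * region_bp
  for (g in seq_len(n_gen)) {
    geno <- haps[odd, core] + haps[odd + 1L, core]
    w <- 1 + s * geno
    parents <- sample.int(n_dip, 2L * n_dip, replace = TRUE, prob = w)
    n_x <- stats::rpois(2L * n_dip, lambda)
    first <- stats::runif(2L * n_dip) < 0.5
    nxt <- matrix(0L, 2L * n_dip, m)
    for (j in seq_len(2L * n_dip)) {
      p <- parents[j]
      if (n_x[j] == 0L) {
        nxt[j, ] <- haps[2L * p - 2L + (if (first[j]) 1L else 2L), ]
      } else {
        seg <- findInterval(positions,
                            sort(stats::runif(n_x[j])) * region_bp)
        use1 <- (seg + !first[j]) %% 2L == 0L
        h1 <- haps[2L * p - 1L, ]
        h2 <- haps[2L * p, ]
        nxt[j, ] <- ifelse(use1, h1, h2)
      }
    }
    haps <- nxt
    if (sum(haps[, core]) == 0L) return(NULL)
  }
  haps
}

#' Simulate a selective sweep in population A
#'
#' Standing variation for the whole of population A (`2 * n_e` founder
#' haplotypes) and the sample from B are drawn from the neutral two-deme
#' coalescent; population A then evolves forward under Wright-Fisher
#' reproduction for `selection$onset_gen` generations with additive selection
#' (fitness 1, 1+s, 1+2s; s = alpha / (2 n_e)) at a core site chosen as the
#' segregating site nearest the region midpoint with founder frequency in
#' [0.1, 0.9], and crossovers Poisson at `recomb_rate` per bp. Finally
#' `n_hap_a` haplotypes are sampled (whole diploids) from A. Replicates in
#' which the favoured allele is lost, in the population or in the final
#' sample, are retried up to 100 times.
#'
#' Sites monomorphic in the emitted combined sample (drift can fix or lose
#' A-private variants during the forward phase) are dropped, so the output
#' can carry fewer than `fixed_s` sites.
#'
#' @param config a [sim_config()] with `selection` set.
#' @return A [haplotype_matrix()] with attributes `core_site` (column index
#'   of the selected site), `core_pos` (bp), `core_p0` / `core_p_final`
#'   (favoured-allele frequency among the founders and in the final A
#'   sample) and `n_retries`.
#' @export
simulate_sweep <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$selection))
    stop("config has no selection; use simulate_neutral()")
  if (!is.null(config$seed)) set.seed(config$seed)
  s <- config$selection$alpha / (2 * config$n_e)
  n_founder <- 2L * as.integer(config$n_e)
  mid <- config$region_bp / 2
  for (try in seq_len(100L)) {
    br <- .coalescent_branches(config, n_a = n_founder, n_b = config$n_hap_b)
    sim <- .place_mutations(br, config)
    if (!ncol(sim$alleles)) next
    a_rows <- seq_len(n_founder)
    founders <- sim$alleles[a_rows, , drop = FALSE]
    p_a <- colMeans(founders)
    cand <- which(p_a >= 0.1 & p_a <= 0.9)
    if (!length(cand)) cand <- which(p_a > 0 & p_a < 1)
    if (!length(cand)) next
    core <- cand[which.min(abs(sim$positions[cand] - mid))]
    swept <- .forward_sweep(founders, core, s, config$selection$onset_gen,
                            config$recomb_rate, config$region_bp,
                            sim$positions)
    if (is.null(swept)) next
    n_ind <- config$n_hap_a %/% 2L
    picked <- sample.int(config$n_e, n_ind)
    rows_a <- as.vector(rbind(2L * picked - 1L, 2L * picked))
    if (config$n_hap_a %% 2L == 1L)
      rows_a <- c(rows_a, 2L * sample.int(config$n_e, 1L) - 1L)
    samp_a <- swept[rows_a, , drop = FALSE]
    if (sum(samp_a[, core]) == 0L) next
    combined <- rbind(samp_a,
                      sim$alleles[-a_rows, , drop = FALSE])
    f <- colMeans(combined)
    poly <- f > 0 & f < 1
    if (!poly[core] || sum(poly) < 2L) next
    mat <- .matrix_from_sim(
      list(alleles = combined[, poly, drop = FALSE],
           positions = sim$positions[poly]), config)
    attr(mat, "core_site") <- sum(poly[seq_len(core)])
    attr(mat, "core_pos") <- sim$positions[core]
    attr(mat, "core_p0") <- p_a[core]
    attr(mat, "core_p_final") <- mean(samp_a[, core])
    attr(mat, "n_retries") <- try - 1L
    return(mat)
  }
  stop("sweep allele lost in 100 consecutive attempts; ",
       "selection too weak for the configured onset?")
}

#' Dispatch a configuration to the matching simulator
#'
#' @param config a [sim_config()].
#' @return A [haplotype_matrix()] from [simulate_sweep()],
#'   [simulate_bottleneck()] or [simulate_neutral()] according to which
#'   optional components are set.
#' @export
simulate_scenario <- function(config) {
  if (!is.null(config$selection)) simulate_sweep(config)
  else if (!is.null(config$bottleneck)) simulate_bottleneck(config)
  else simulate_neutral(config)
}

#' Run the demographic calibration scenarios
#'
#' Simulates `n_replicates` data sets per scenario, scans each with
#' [xpehh_scan()], and summarizes the pooled score distributions: quantiles
#' (1, 5, 25, 50, 75, 95, 99%) and pairwise two-sample Kolmogorov-Smirnov
#' distances between scenarios. Fully reproducible: per-replicate seeds are
#' drawn once from `seed`.
#'
#' Scores are reported on two scales. `std` is each replicate's internal
#' standardization (mean 0, variance 1 within the replicate) -- on this
#' scale the scenario distributions are expected to closely match whatever
#' the demography, since each short region is its own reference. When a
#' scenario named `"neutral"` is present, `std_null` additionally
#' standardizes every raw log-ratio by the pooled neutral moments, the
#' analogue of genome-wide standardization against a mostly neutral genome;
#' quantiles and KS distances are computed on `std_null` in that case (on
#' `std` otherwise).
#'
#' @param configs named list of [sim_config()] objects, e.g.
#'   [default_scenarios()].
#' @param n_replicates replicates per scenario.
#' @param seed integer seed for the whole experiment.
#' @param cutoff EHH truncation cutoff passed to [xpehh_scan()].
#' @param keep_matrices keep the simulated [haplotype_matrix()] objects
#'   (memory-hungry; default drops them once scanned).
#' @return An object of class `scenario_scan_set`: list with
#'   \describe{
#'     \item{scenarios}{per scenario: `config`, `scores` (data.frame `rep`,
#'       `pos`, `raw`, `std` and, when a neutral scenario is present,
#'       `std_null`), `core_pos` (per-replicate planted core position, `NA`
#'       when neutral), optionally `matrices`.}
#'     \item{quantiles}{scenario x quantile matrix of pooled scores.}
#'     \item{ks}{scenario x scenario matrix of KS distances.}
#'     \item{null_norm}{`c(mean, sd)` of pooled neutral raw scores, if any.}
#'     \item{seed, n_replicates}{the inputs.}
#'   }
#' @export
run_scenarios <- function(configs, n_replicates = 200, seed = 1,
                          cutoff = 0.05, keep_matrices = FALSE) {
  stopifnot(length(configs) >= 1L, !is.null(names(configs)))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max,
                      length(configs) * n_replicates)
  dim(seeds) <- c(n_replicates, length(configs))
  scen <- vector("list", length(configs))
  names(scen) <- names(configs)
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    score_list <- vector("list", n_replicates)
    core_pos <- rep(NA_real_, n_replicates)
    mats <- if (keep_matrices) vector("list", n_replicates) else NULL
    for (j in seq_len(n_replicates)) {
      cfg$seed <- seeds[j, i]
      mat <- simulate_scenario(cfg)
      scan <- xpehh_scan(mat, cutoff = cutoff)
      score_list[[j]] <- data.frame(rep = j, pos = scan$pos,
                                    raw = scan$raw,
                                    std = scan$std)[scan$defined, ]
      if (!is.null(attr(mat, "core_pos")))
        core_pos[j] <- attr(mat, "core_pos")
      if (keep_matrices) mats[[j]] <- mat
    }
    scen[[i]] <- list(config = configs[[i]],
                      scores = do.call(rbind, score_list),
                      core_pos = core_pos, matrices = mats)
  }
  null_norm <- NULL
  if ("neutral" %in% names(scen)) {
    nr <- scen[["neutral"]]$scores$raw
    null_norm <- c(mean = mean(nr), sd = stats::sd(nr))
    for (i in seq_along(scen))
      scen[[i]]$scores$std_null <-
        (scen[[i]]$scores$raw - null_norm[1L]) / null_norm[2L]
  }
  pick <- function(s) if (is.null(null_norm)) s$scores$std else
    s$scores$std_null
  probs <- c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99)
  qs <- t(vapply(scen, function(s) stats::quantile(pick(s), probs),
                 numeric(length(probs))))
  ks <- matrix(0, length(scen), length(scen),
               dimnames = list(names(scen), names(scen)))
  for (a in seq_along(scen)) for (b in seq_along(scen)) if (a < b) {
    d <- suppressWarnings(stats::ks.test(pick(scen[[a]]),
                                         pick(scen[[b]]))$statistic)
    ks[a, b] <- ks[b, a] <- unname(d)
  }
  structure(list(scenarios = scen, quantiles = qs, ks = ks,
                 null_norm = null_norm, seed = seed,
                 n_replicates = n_replicates),
            class = "scenario_scan_set")
}

#' @export
print.scenario_scan_set <- function(x, ...) {
  cat(sprintf("scenario_scan_set: %d scenarios x %d replicates (seed %d)\n",
              length(x$scenarios), x$n_replicates, x$seed))
  cat("pooled XP-EHH quantiles:\n")
  print(round(x$quantiles, 3))
  cat("pairwise KS distances:\n")
  print(round(x$ks, 3))
  invisible(x)
}
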