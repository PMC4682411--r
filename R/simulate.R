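#' Configuration for the synthetic screen generator
#'
#' Defines a joint simulation of the three pipeline inputs — drug screen,
#' kinase-binding panel and expression table — with known planted kinase
#' dependencies. Defaults mirror the scale of a published TNBC screen
#' setting (12 cell lines, 72 usable compounds, ~300-kinase panel); tests
#' typically run a reduced 4 x 20 x 50 scale.
#'
#' Potency and response values live on the log scale by nature, so EC50
#' noise is lognormal and the dependency effect multiplicative: compounds
#' that potently inhibit a cell line's planted kinase have their EC50 in
#' that cell line divided by `effect`.
#'
#' @param n_cell_lines,n_compounds,n_kinases panel dimensions (all >= 2).
#' @param targets_per_compound mean number of measured kinase targets per
#'   compound (promiscuity; 1 + Poisson(mean - 1) draws).
#' @param planted named list, cell line -> planted dependent kinase labels.
#'   `NULL` (default) plants one distinct random kinase per cell line;
#'   `list()` plants nothing (null model).
#' @param planted_hitters number of compounds guaranteed a sub-micromolar Kd
#'   against each planted kinase (default 6).
#' @param effect EC50 fold-shift for compounds hitting a planted kinase
#'   (default 20; 1 = null model).
#' @param noise_sd lognormal noise SD of log10 EC50 (default 0.25).
#' @param baseline_log10_ec50 mean log10 EC50 (uM) of unshifted compounds
#'   (default 1.0, i.e. 10 uM — insensitive under default bin boundaries).
#' @param kd_meanlog10,kd_sdlog10 log10-normal Kd distribution of random
#'   compound-kinase measurements (defaults -0.3 and 0.8).
#' @param silent_frac fraction of non-planted kinases transcriptionally
#'   silenced (default 0.3).
#' @param expr_mu_on,expr_mu_off,expr_sd log2 expression means for expressed
#'   vs silenced kinases and their SD (defaults 8, 3, 0.5).
#' @param max_dose top screening concentration in uM; simulated EC50s above
#'   it become inactive-at-max-dose entries (default 30).
#' @param missing_frac fraction of screen cells left untested (default 0.02).
#' @param seed integer seed; the generator is fully seed-deterministic
#'   (Mersenne-Twister / Inversion, pinned).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cell_lines = 12L, n_compounds = 72L,
                       n_kinases = 300L, targets_per_compound = 4,
                       planted = NULL, planted_hitters = 6L, effect = 20,
                       noise_sd = 0.25, baseline_log10_ec50 = 1.0,
                       kd_meanlog10 = -0.3, kd_sdlog10 = 0.8,
                       silent_frac = 0.3, expr_mu_on = 8, expr_mu_off = 3,
                       expr_sd = 0.5, max_dose = 30, missing_frac = 0.02,
                       seed = 1L) {
  stopifnot(is_count(n_cell_lines, 2), is_count(n_compounds, 2),
            is_count(n_kinases, 2), targets_per_compound >= 1,
            is_count(planted_hitters, 1), effect >= 1, noise_sd >= 0,
            silent_frac >= 0, silent_frac < 1, expr_sd >= 0, max_dose > 0,
            missing_frac >= 0, missing_frac < 1, is_count(seed))
  if (!is.null(planted) && !is.list(planted))
    stop("`planted` must be NULL or a named list cell line -> kinases")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a screen/binding/expression triple with planted dependencies
#'
#' Generates, under one seed:
#' * a binding panel: every compound measures a random kinase subset with
#'   lognormal Kd (some sub-micromolar); each planted kinase is additionally
#'   guaranteed `planted_hitters` compounds with Kd < 1 uM;
#' * a drug screen: baseline log10 EC50 ~ Normal(`baseline_log10_ec50`,
#'   `noise_sd`); compounds that potently inhibit a cell line's planted
#'   kinase have their EC50 divided by `effect` in that cell line; EC50s
#'   above `max_dose` become inactive entries and a `missing_frac` fraction
#'   of cells is left untested;
#' * an expression table in which planted kinases are always expressed and a
#'   `silent_frac` fraction of the others is silenced;
#' * a truth table of the planted (cell line, kinase) pairs.
#'
#' Consistency is asserted at generation time: every planted pair has at
#' least one compound with Kd < 1 uM against it.
#'
#' @param config a [sim_config()].
#' @return list of class `kar_simulation` with elements `screen`
#'   ([drug_screen()]), `binding` ([binding_profile()]), `expression`
#'   (matrix), `truth` (data.frame `cell_line`, `kinase`,
#'   `n_potent_compounds`) and `config`. The RNG algorithm identifier is
#'   recorded in attribute `rng_kind`.
#' @export
simulate_kinase_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_seed(config$seed, {
    cls <- sprintf("CL%02d", seq_len(config$n_cell_lines))
    cmp <- sprintf("DRUG%03d", seq_len(config$n_compounds))
    kin <- sprintf("KIN%03d", seq_len(config$n_kinases))

    planted <- config$planted
    if (is.null(planted)) {
      if (config$n_kinases < config$n_cell_lines)
        stop("cannot plant distinct kinases: fewer kinases than cell lines")
      planted <- stats::setNames(as.list(sample(kin, config$n_cell_lines)), cls)
    } else {
      if (length(planted) > 0 &&
          (is.null(names(planted)) || !all(names(planted) %in% cls)))
        stop("`planted` names must be simulated cell-line identifiers (",
             paste(utils::head(cls, 3), collapse = ", "), ", ...)")
      bad <- setdiff(unlist(planted), kin)
      if (length(bad) > 0L)
        stop("planted kinase(s) outside the kinase universe: ",
             paste(bad, collapse = ", "))
    }

    # binding panel: Kd in uM, lognormal; stored per compound as named vector
    kd <- stats::setNames(vector("list", length(cmp)), cmp)
    for (d in cmp) {
      n_t <- min(1L + stats::rpois(1, config$targets_per_compound - 1),
                 config$n_kinases)
      targets <- sample(kin, n_t)
      kd[[d]] <- stats::setNames(
        10^stats::rnorm(n_t, config$kd_meanlog10, config$kd_sdlog10), targets)
    }
    # guarantee potent hitters for every planted kinase
    for (k in unique(unlist(planted))) {
      hitters <- sample(cmp, min(config$planted_hitters, length(cmp)))
      for (d in hitters) {
        potent <- 10^stats::runif(1, -1.5, -0.15)  # 0.03 .. 0.7 uM
        kd[[d]][k] <- min(kd[[d]][k], potent, na.rm = TRUE)
      }
    }
    binding <- binding_profile(data.frame(
      compound = rep(cmp, lengths(kd)),
      kinase = unlist(lapply(kd, names), use.names = FALSE),
      value = unlist(kd, use.names = FALSE),
      measure = "Kd_uM", stringsAsFactors = FALSE))

    # which compounds potently (Kd < 1 uM) inhibit which kinases
    potent_hits <- lapply(kd, function(v) names(v)[v < 1])

    log_ec50 <- matrix(
      stats::rnorm(length(cls) * length(cmp), config$baseline_log10_ec50,
                   config$noise_sd),
      length(cls), length(cmp), dimnames = list(cls, cmp))
    for (cl in names(planted)) {
      hit <- vapply(cmp, function(d)
        any(planted[[cl]] %in% potent_hits[[d]]), logical(1))
      log_ec50[cl, hit] <- log_ec50[cl, hit] - log10(config$effect)
    }
    ec50 <- 10^log_ec50
    inactive <- ec50 > config$max_dose
    ec50[inactive] <- NA_real_
    if (config$missing_frac > 0) {
      candidates <- which(!inactive)
      n_miss <- floor(config$missing_frac * length(ec50))
      if (n_miss > 0 && length(candidates) > n_miss) {
        miss <- sample(candidates, n_miss)
        ec50[miss] <- NA_real_
      }
    }
    screen <- drug_screen(ec50, inactive)

    planted_all <- unique(unlist(planted))
    silent_pool <- setdiff(kin, planted_all)
    silenced <- sample(silent_pool,
                       min(floor(config$silent_frac * config$n_kinases),
                           length(silent_pool)))
    mu <- ifelse(kin %in% silenced, config$expr_mu_off, config$expr_mu_on)
    expr <- matrix(stats::rnorm(length(kin) * length(cls), mu, config$expr_sd),
                   length(kin), length(cls), dimnames = list(kin, cls))
    expr <- expression_table(expr)

    truth <- if (length(planted) == 0L) {
      data.frame(cell_line = character(0), kinase = character(0),
                 n_potent_compounds = integer(0), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(names(planted), function(cl) {
        data.frame(cell_line = cl, kinase = planted[[cl]],
                   n_potent_compounds = vapply(planted[[cl]], function(k)
                     sum(vapply(potent_hits, function(h) k %in% h, logical(1))),
                     integer(1)),
                   stringsAsFactors = FALSE)
      }))
    }
    rownames(truth) <- NULL
    if (nrow(truth) > 0 && any(truth$n_potent_compounds < 1))
      stop("internal inconsistency: a planted kinase has no potent compound")

    structure(list(screen = screen, binding = binding, expression = expr,
                   truth = truth, config = config),
              class = "kar_simulation",
              rng_kind = "Mersenne-Twister/Inversion")
  })
}

#' Simulate the matching null model (no planted dependencies)
#'
#' Identical generator with an empty planted map: no compound's EC50 is
#' shifted, so kinase-sensitivity associations arise by chance only. Used
#' for false-positive-rate calibration.
#'
#' @param config a [sim_config()]; its `planted` entry is ignored.
#' @return a `kar_simulation` with an empty truth table.
#' @export
null_simulate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$planted <- list()
  simulate_kinase_screen(config)
}

#' Write a simulated data set as the pipeline's input TSVs
#'
#' @param sim a `kar_simulation`.
#' @param dir output directory; emits `screen.tsv`, `binding.tsv`,
#'   `expression.tsv`, `truth.tsv`.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "screen.tsv"), file.path(dir, "binding.tsv"),
             file.path(dir, "expression.tsv"), file.path(dir, "truth.tsv"))
  write_drug_screen(sim$screen, paths[1])
  write_binding(sim$binding, paths[2])
  write_expression(sim$expression, paths[3])
  utils::write.table(sim$truth, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
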