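#' Validate and normalise a synthetic-study configuration
#'
#' Fills every documented default, range-checks user-supplied values (errors
#' name the offending field and bound), and attaches a provenance header
#' (package version, seed, config hash) that [run_synthetic_study()] stamps
#' into every output. One global seed is expanded into fixed per-stage
#' substreams so stages can be rerun independently with stable results.
#'
#' @param config Named list of overrides; an empty list yields the full
#'   default study (two genotypes at two ages, parameters from the published
#'   best fits where available, package defaults elsewhere).
#' @return The normalised config, class `study_config`, with a `provenance`
#'   element.
#' @export
validate_study_config <- function(config = list()) {
  defaults <- list(
    seed = 1L,
    # bAP attenuation: published best-fit (A, b) per genotype and age
    bap = list(
      "5wk" = list(
        wildtype = list(a0_mv = 72.86, b_amp = 0.0376),
        mutant   = list(a0_mv = 75.40, b_amp = 0.0215)
      ),
      "15wk" = list(
        wildtype = list(a0_mv = 75.64, b_amp = 0.0385),
        mutant   = list(a0_mv = 72.99, b_amp = 0.0230)
      )
    ),
    bap_distances_um = seq(10, 120, by = 10),
    bap_noise_sd_amp_mv = 2,
    bap_hw0_ms = 0.35,
    bap_b_hw = list(wildtype = 0.003, mutant = 0.005),
    bap_noise_sd_hw_ms = 0.02,
    # two-compartment circuits: mutant loses distal dendritic capacitance
    circuit = list(
      wildtype = list(c1_pf = 112.5, c2_pf = 500, r1_mohm = 20 / 3, r2_mohm = 40 / 3),
      mutant   = list(c1_pf = 112.5, c2_pf = 300, r1_mohm = 20 / 3, r2_mohm = 40 / 3)
    ),
    cap_noise_sd_pa = 5,
    cap_n_sweeps = 10,
    cap_r_input_mohm = 150,
    # calcium-spike thresholds: mutant requires less current
    ca_threshold_pa = list(wildtype = 900, mutant = 600),
    ca_r_input_mohm = 100,
    ca_step_levels_pa = seq(100, 1200, by = 100),
    # gene screen
    n_genes = 2000,
    n_signif_channels = list("5wk" = 12, "12wk" = 18),
    n_persistent = 6,
    q_cut = 0.05,
    ljp_mv = 10,
    out_format = "csv"
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)

  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    stop("`seed`: must be a single integer", call. = FALSE)
  }
  if (cfg$q_cut < 0 || cfg$q_cut > 1) {
    stop("`q_cut`: must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$bap_noise_sd_amp_mv < 0) stop("`bap_noise_sd_amp_mv`: must be >= 0", call. = FALSE)
  if (cfg$cap_n_sweeps < 1) stop("`cap_n_sweeps`: must be >= 1", call. = FALSE)
  if (!cfg$out_format %in% c("csv", "json")) {
    stop('`out_format`: must be "csv" or "json"', call. = FALSE)
  }
  if (cfg$ljp_mv == 0) warning("ljp_mv = 0 accepted, but no junction-potential correction is non-standard")

  cfg$seed <- as.integer(cfg$seed)
  # fixed per-stage substreams derived from the global seed
  offsets <- c(capacitance = 1, bap = 2, spikes = 3, calcium = 4, genes = 5)
  cfg$stage_seeds <- stats::setNames(
    as.integer((as.numeric(cfg$seed) * 1000 + offsets) %% .Machine$integer.max),
    names(offsets))
  cfg$provenance <- list(
    package = "dendricap",
    version = as.character(utils::packageVersion("dendricap")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "provenance")])
  )
  structure(cfg, class = "study_config")
}

#' Run the full synthetic study
#'
#' Generates synthetic cohorts for two genotypes (wild-type and mutant) at
#' two ages, runs every analysis stage on them, and reports recovered
#' against planted parameters together with all test statistics:
#' \itemize{
#'   \item capacitance: simulated transient sweeps per genotype, averaged,
#'     filtered, leak-corrected, biexponentially fitted and mapped to
#'     (C1, C2, R1, R2); recovered vs planted values and relative errors.
#'   \item attenuation: per-cell bAP amplitude and half-width datasets per
#'     age, single-exponent fits with length constants, and the extra
#'     sum-of-squares F test comparing genotypes.
#'   \item spike features: a stereotyped spike trace analysed for amplitude
#'     and half-width against planted truth.
#'   \item calcium spikes: step families per genotype, threshold currents
#'     and windowed input resistance.
#'   \item gene screen: synthetic 5wk/12wk tables subset to the 145-gene
#'     channel list, flagged at q <= 0.05, with the persistent set.
#' }
#'
#' @param config A [validate_study_config()] result or a plain list of
#'   overrides.
#' @param out_dir Optional directory; when given, every stage table is
#'   written there as CSV with the provenance header in a comment line.
#' @return A list of class `dendricap_study` of per-stage tibbles plus
#'   `config`.
#' @export
run_synthetic_study <- function(config = list(), out_dir = NULL) {
  cfg <- if (inherits(config, "study_config")) config else validate_study_config(config)
  genotypes <- c("wildtype", "mutant")
  ss <- cfg$stage_seeds

  ## --- capacitance stage -------------------------------------------------
  capacitance <- purrr::imap_dfr(cfg$circuit, function(circ, g) {
    spec <- sim_circuit_spec(
      c1_pf = circ$c1_pf, c2_pf = circ$c2_pf, r1_mohm = circ$r1_mohm,
      r2_mohm = circ$r2_mohm, r_input_mohm = cfg$cap_r_input_mohm,
      noise_sd_pa = cfg$cap_noise_sd_pa, n_sweeps = cfg$cap_n_sweeps,
      seed = ss[["capacitance"]] + match(g, genotypes))
    sweeps <- simulate_capacitance_sweeps(spec)
    transient <- preprocess_transient(sweeps, r_input_mohm = cfg$cap_r_input_mohm)
    fit <- fit_biexponential(transient)
    comp <- derive_compartments(fit)
    tibble::tibble(
      group = g,
      qc = qc_cell(cfg$cap_r_input_mohm),
      c1_pf = abs(comp$c1_pf), c2_pf = abs(comp$c2_pf),
      r1_mohm = comp$r1_mohm, r2_mohm = comp$r2_mohm,
      c1_planted_pf = circ$c1_pf, c2_planted_pf = circ$c2_pf,
      r1_planted_mohm = circ$r1_mohm, r2_planted_mohm = circ$r2_mohm,
      c1_rel_err = abs(comp$c1_pf - circ$c1_pf) / circ$c1_pf,
      c2_rel_err = abs(comp$c2_pf - circ$c2_pf) / circ$c2_pf,
      converged = fit$converged
    )
  })

  ## --- attenuation stage -------------------------------------------------
  atten_data <- purrr::imap_dfr(cfg$bap, function(by_geno, age) {
    purrr::imap_dfr(by_geno, function(par, g) {
      spec <- sim_bap_spec(
        a0_mv = par$a0_mv, b_amp = par$b_amp, hw0_ms = cfg$bap_hw0_ms,
        b_hw = cfg$bap_b_hw[[g]], distances_um = cfg$bap_distances_um,
        noise_sd_amp_mv = cfg$bap_noise_sd_amp_mv,
        noise_sd_hw_ms = cfg$bap_noise_sd_hw_ms,
        seed = ss[["bap"]] + 10L * match(age, names(cfg$bap)) + match(g, genotypes))
      dplyr::mutate(simulate_bap_dataset(spec, group = g), age = age)
    })
  })
  attenuation <- purrr::map_dfr(names(cfg$bap), function(age) {
    d <- dplyr::filter(atten_data, .data$age == .env$age)
    ft_amp <- extra_ss_f_test(d, sign = "decay")
    ft_hw <- extra_ss_f_test(d, y = halfwidth_ms, sign = "growth")
    purrr::map_dfr(genotypes, function(g) {
      fit <- ft_amp$per_group[[g]]
      tibble::tibble(
        age = age, group = g,
        a_mv = fit$a, b_per_um = fit$b,
        lambda_um = round(length_constant(fit), 1),
        lambda_planted_um = round(1 / cfg$bap[[age]][[g]]$b_amp, 1),
        r2 = fit$r2,
        f_amplitude = ft_amp$f_stat, p_amplitude = ft_amp$p_value,
        f_halfwidth = ft_hw$f_stat, p_halfwidth = ft_hw$p_value
      )
    })
  })

  ## --- spike-feature stage -----------------------------------------------
  shape <- spike_shape()
  sim_sp <- simulate_spike_trace(shape, n_spikes = 10, duration_ms = 600,
                                 rate_hz = 20, noise_sd_mv = 0,
                                 seed = ss[["spikes"]])
  cfg_sp <- spike_config(ljp_mv = cfg$ljp_mv)
  amp <- trace_amplitude_stats(sim_sp$trace, cfg_sp, duration_ms = 600)
  hw <- first_n_spike_halfwidths(sim_sp$trace, cfg_sp, n = 5)
  spikes <- tibble::tibble(
    n_spikes = nrow(amp$per_spike),
    mean_amplitude_mv = amp$mean_amplitude_mv,
    amplitude_planted_mv = shape$amplitude_mv,
    mean_halfwidth_ms = hw$mean_halfwidth_ms,
    halfwidth_planted_ms = shape$half_width_ms
  )

  ## --- calcium-spike stage -----------------------------------------------
  calcium <- purrr::imap_dfr(cfg$ca_threshold_pa, function(thr, g) {
    seed_g <- ss[["calcium"]] + match(g, genotypes)
    fam <- simulate_castep_family(sim_ca_spec(
      threshold_pa = thr, r_input_mohm = cfg$ca_r_input_mohm,
      step_levels_pa = cfg$ca_step_levels_pa, seed = seed_g))
    th <- threshold_current(fam)
    # separate small-step I-O family inside the -80..-75 mV window
    rin_steps <- with(list(r = cfg$ca_r_input_mohm),
                      seq(1000 / r, 4000 / r, length.out = 4))
    fam_rin <- simulate_castep_family(sim_ca_spec(
      threshold_pa = 10 * max(rin_steps), r_input_mohm = cfg$ca_r_input_mohm,
      step_levels_pa = rin_steps, seed = seed_g + 100L))
    rin <- input_resistance(fam_rin)
    tibble::tibble(
      group = g,
      threshold_pa = th$threshold_pa,
      threshold_planted_pa = thr,
      threshold_reached = th$reached,
      rin_mohm = rin$rin_mohm,
      rin_planted_mohm = cfg$ca_r_input_mohm
    )
  })

  ## --- gene-screen stage -------------------------------------------------
  channels <- channel_gene_list()
  tps <- names(cfg$n_signif_channels)
  # plant the significant sets with a fixed overlap (the persistent set)
  sig_sets <- with_local_seed(ss[["genes"]], {
    n5 <- cfg$n_signif_channels[[1]]
    n12 <- cfg$n_signif_channels[[2]]
    n_pers <- min(cfg$n_persistent, n5, n12)
    hits5 <- sample(channels$gene, n5)
    shared <- sample(hits5, n_pers)
    hits12 <- c(shared, sample(setdiff(channels$gene, hits5), n12 - n_pers))
    stats::setNames(list(hits5, hits12), tps)
  })
  tabs <- purrr::imap(sig_sets, function(hits, tp) {
    simulate_expression_table(
      n_genes = cfg$n_genes, channel_list = channels,
      signif_channel_genes = hits, timepoint = tp,
      seed = ss[["genes"]] + match(tp, tps))
  })
  flagged <- purrr::map(tabs, function(tb) {
    flag_significant(subset_channels(tb, channels), q_cut = cfg$q_cut)
  })
  persistent <- persistent_dysregulated(flagged[[1]], flagged[[2]])
  genes <- tibble::tibble(
    timepoint = names(flagged),
    n_channel_genes = purrr::map_int(flagged, nrow),
    n_significant = purrr::map_int(flagged, ~ sum(isTRUE_v(.x$significant))),
    n_planted = unlist(cfg$n_signif_channels),
    n_persistent = nrow(persistent)
  )

  report <- structure(list(
    capacitance = capacitance,
    attenuation = attenuation,
    attenuation_data = atten_data,
    spikes = spikes,
    calcium = calcium,
    genes = genes,
    persistent_genes = persistent,
    config = cfg
  ), class = "dendricap_study")

  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

# every output table carries the provenance header as a leading comment
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- report$config$provenance
  header <- sprintf("# %s %s seed=%d config=%s", prov$package, prov$version,
                    prov$seed, prov$config_hash)
  tabs <- c("capacitance", "attenuation", "attenuation_data", "spikes",
            "calcium", "genes", "persistent_genes")
  for (nm in tabs) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    writeLines(header, path)
    suppressWarnings(utils::write.table(
      report[[nm]], path, append = TRUE, sep = ",", row.names = FALSE,
      quote = TRUE))
  }
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.dendricap_study <- function(x, ...) {
  cat("Synthetic dendritic-excitability study\n")
  cat(sprintf("  seed %d, config %s\n", x$config$seed,
              x$config$provenance$config_hash))
  cat("\nAttenuation (bAP amplitude vs distance):\n")
  print(x$attenuation, n = Inf)
  cat("\nCapacitance recovery:\n")
  print(dplyr::select(x$capacitance, dplyr::all_of(
    c("group", "c1_pf", "c2_pf", "c1_rel_err", "c2_rel_err"))))
  cat("\nCalcium-spike thresholds:\n")
  print(x$calcium)
  cat("\nChannel gene screen:\n")
  print(x$genes)
  invisible(x)
}
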