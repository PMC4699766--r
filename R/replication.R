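# End-to-end replication: simulate -> gate -> describe -> compare -> invert.

#' Run the full study replication
#'
#' Orchestrates the whole pipeline on synthetic data: simulate the multi-dose
#' study, gate to isolated G0/G1 nuclei, compute per-dose count statistics
#' and spread fold changes, fit the dose response on replicate means, sample
#' specific energies for each comparison volume at each dose (with sample
#' sizes matched to the gated populations) and summarize them, build Q-Q
#' comparisons of counts against the matching-volume energies, and invert
#' the spread relation on the observed count `sd_rel` to recover the
#' matching target volume. Everything derives deterministically from `seed`:
#' the returned report is byte-identical across runs (serialize it with
#' [write_report()]).
#'
#' @param model A calibrated [specific_energy_model()]
#'   (default [co60_default_model()]).
#' @param doses,n_per_dose Study design (defaults as in [simulate_study()]).
#' @param volumes Comparison target volumes, um^3 (defaults: whole nucleus
#'   293.7, DNA molecule 8.5, matching volume 1.6).
#' @param config Template [population_config()].
#' @param seed Integer seed.
#' @param gate Apply the auto-derived G0/G1 gate (default TRUE).
#' @return A nested list report (class `replication_report`).
#' @export
#' @examples
#' \donttest{
#' rep <- run_replication(seed = 1)
#' rep$inverted_volume$mean_um3
#' }
run_replication <- function(model = co60_default_model(),
                            doses = c(0, 0.5, 1, 2),
                            n_per_dose = c(25114L, 8242L, 8993L, 9010L),
                            volumes = c(293.7, 8.5, 1.6),
                            config = population_config(1, 0),
                            seed = 1L,
                            gate = TRUE) {
  seeds <- split_seed(seed, 2L)
  study <- simulate_study(model, doses = doses, n_per_dose = n_per_dose,
                          config = config, seed = seeds[1])
  if (gate) {
    gr <- auto_gate(study)
    kept <- gr$records[gr$records$selected, , drop = FALSE]
    gate_info <- list(thresholds = as.list(attr(gr, "thresholds")),
                      counts = as.list(gr$counts))
  } else {
    kept <- study
    gate_info <- NULL
  }

  # Per-dose count statistics (pooled over replicates)
  count_stats <- do.call(rbind, lapply(doses, function(d) {
    st <- describe_counts(kept$rif_count[kept$dose_nominal_Gy == d])
    cbind(tibble::tibble(dose_Gy = d), st)
  }))

  irradiated <- doses[doses > 0]
  folds <- fold_change_series(count_stats[count_stats$dose_Gy > 0, ])

  # Dose response on replicate means
  rep_means <- stats::aggregate(rif_count ~ replicate_id + dose_nominal_Gy,
                                data = kept, FUN = mean)
  names(rep_means) <- c("replicate_id", "dose_Gy", "mean_rif")
  dr <- fit_dose_response(rep_means)

  # Specific-energy populations for each comparison volume, n matched to the
  # gated count populations
  energy_seeds <- split_seed(seeds[2], length(volumes) * length(irradiated))
  k <- 0L
  energy_stats <- list()
  qq <- list()
  match_vol <- volumes[length(volumes)]
  for (v in volumes) {
    for (d in irradiated) {
      k <- k + 1L
      n_d <- sum(kept$dose_nominal_Gy == d)
      z <- sample_specific_energy(energy_spec_for(model, v, d), n_d,
                                  seed = energy_seeds[k])
      st <- describe_counts(z)
      energy_stats[[k]] <- cbind(tibble::tibble(V = v, dose_Gy = d), st)
      if (v == match_vol) {
        q <- qq_compare(kept$rif_count[kept$dose_nominal_Gy == d], z)
        qq[[paste0("D", d)]] <- list(slope = q$slope, intercept = q$intercept,
                                     r_squared = q$r_squared)
      }
    }
  }
  energy_stats <- do.call(rbind, energy_stats)

  # Invert the spread relation on the observed count spreads
  obs <- count_stats[count_stats$dose_Gy > 0, ]
  v_inv <- invert_target_volume(model, obs$sd_rel, obs$dose_Gy)

  structure(list(
    model = list(k1 = model$k1, k2 = model$k2, beam_label = model$beam_label),
    design = list(doses = doses, n_per_dose = n_per_dose, volumes = volumes,
                  seed = seed, config = unclass(config)),
    gate = gate_info,
    count_stats = count_stats,
    fold_changes = folds,
    dose_response = list(slope = dr$slope, intercept = dr$intercept,
                         r_squared = dr$r_squared,
                         slope_replicate_level = dr$slope_replicate_level,
                         per_dose = dr$per_dose),
    energy_stats = energy_stats,
    qq = qq,
    inverted_volume = list(per_dose = tibble::tibble(dose_Gy = obs$dose_Gy,
                                                     sd_rel_obs = obs$sd_rel,
                                                     volume_um3 = v_inv),
                           mean_um3 = mean(v_inv))),
    class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat("<replication_report>\n")
  cat(sprintf("  model: %s, k1 = %.4g, k2 = %.4g\n",
              x$model$beam_label, x$model$k1, x$model$k2))
  cat(sprintf("  doses (Gy): %s; gated nuclei per dose: %s\n",
              paste(x$design$doses, collapse = ", "),
              paste(x$count_stats$n, collapse = ", ")))
  cat(sprintf("  dose response: %.2f RIF/Gy (intercept %.2f, R^2 %.4f)\n",
              x$dose_response$slope, x$dose_response$intercept,
              x$dose_response$r_squared))
  cat(sprintf("  count sd_rel: %s\n",
              paste(sprintf("%.3f", x$count_stats$sd_rel), collapse = ", ")))
  cat(sprintf("  inverted matching volume: %.2f um^3 (per dose: %s)\n",
              x$inverted_volume$mean_um3,
              paste(sprintf("%.2f", x$inverted_volume$per_dose$volume_um3),
                    collapse = ", ")))
  invisible(x)
}

#' Serialize a replication report to JSON
#'
#' Deterministic (no timestamps, full precision), so a fixed-seed report is
#' byte-identical across runs.
#'
#' @param report A `replication_report` (or any serializable list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns", na = "null")
  invisible(path)
}
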