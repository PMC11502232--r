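# End-to-end pipeline: features -> stability-selected clustering ->
# silhouette filtering -> population naming -> LFP epochs -> CFR table.

.stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    # abort cleanly: remove partial outputs before rethrowing
    unlink(list.files(out_dir, full.names = TRUE), recursive = TRUE)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Reads the canonical CSV/binary inputs, builds the time-warped feature
#' matrix, scans clustering stability, clusters at the variance-adjusted
#' optimum, filters cells by silhouette consistency, names the
#' populations, detects gamma events and nonrhythmic epochs in the LFP
#' (when given), computes the per-pair CFR table with its shuffle null,
#' and writes everything to `out_dir`. All stochastic stages are seeded
#' from `config$master_seed`, so identical inputs and configuration
#' reproduce every output byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param spikes_csv,ethogram_csv input paths (see [read_spike_csv()],
#'   [read_ethogram_csv()]).
#' @param lfp_bin optional flat int16 LFP path (see [read_lfp_flat()]).
#' @param lfp_fs_hz,lfp_session LFP sampling rate and session id.
#' @param out_dir output directory (created if needed).
#' @param max_pairs cap on the number of cross-shank pairs scored in the
#'   CFR stage.
#' @return Invisibly, a list with the in-memory results (`features`,
#'   `stability`, `solution`, `silhouette`, `profile`, `epochs`,
#'   `cfr_table`, `group_tests`).
#' @export
run_pipeline <- function(config, spikes_csv, ethogram_csv, lfp_bin = NULL,
                         lfp_fs_hz = 1250, lfp_session = NULL,
                         out_dir, max_pairs = Inf) {
  stopifnot(inherits(config, "lh_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$master_seed
  log_lines <- c("lhensemble pipeline log",
                 paste0("parameter ", names(config), " = ",
                        vapply(config, function(v) paste(deparse(v), collapse = ""),
                               character(1))))

  inputs <- .stage("read_inputs", out_dir, {
    ds <- read_spike_csv(spikes_csv)
    et <- read_ethogram_csv(ethogram_csv)
    shared <- intersect(ds$session_spans$session_id,
                        unique(et$episodes$session_id))
    if (length(shared) == 0L) stop("spike and ethogram files share no session ids")
    list(ds = ds, et = et)
  })
  ds <- inputs$ds; et <- inputs$et

  feats <- .stage("features", out_dir,
                  build_feature_matrix(ds, et, config))

  stab <- .stage("stability_scan", out_dir,
                 stability_scan(feats$reduced, config$cluster_range,
                                config$knn_range, config$n_bootstrap,
                                config$subsample_fraction,
                                seed = derive_seed(seed, 2L)))
  sel <- stab$selected$by_mean_over_sd

  sil <- .stage("silhouette_filter", out_dir,
                silhouette_filter(feats$reduced, sel$k, sel$knn,
                                  config$silhouette_iters,
                                  config$silhouette_min_pass,
                                  seed = derive_seed(seed, 3L)))
  solution <- sil$reference

  profile <- .stage("label_populations", out_dir, {
    keep <- sil$retained
    bv <- lapply(feats$behavior_vectors, function(m) m[keep, , drop = FALSE])
    label_populations(bv, solution$labels[keep])
  })

  labels_df <- data.frame(
    session_id = feats$cells$session_id,
    cell_id = feats$cells$cell_id,
    cluster = solution$labels,
    population = profile$name[match(solution$labels, profile$cluster)],
    retained = sil$retained,
    stringsAsFactors = FALSE)
  labels_df$population[!labels_df$retained] <- NA_character_

  epochs <- list(); cfr_table <- NULL; group_tests <- NULL
  if (!is.null(lfp_bin)) {
    epochs <- .stage("detect_epochs", out_dir, {
      sid <- lfp_session %||% ds$session_spans$session_id[1L]
      lfp <- read_lfp_flat(lfp_bin, fs_hz = lfp_fs_hz, session_id = sid)
      ev <- lapply(names(config$bands), function(bn) {
        env <- band_envelope(lfp, config$bands[[bn]])
        detect_events(env, config$detect_sd, config$edge_sd,
                      config$min_event_ms, label = bn, session_id = sid)
      })
      names(ev) <- names(config$bands)
      ev$nonrhythmic <- detect_nonrhythmic(
        lfp, config$nonrhythmic_bands, config$nonrhythmic_sd,
        config$min_nonrhythmic_ms, exclude = ev)
      ev
    })

    cfr_out <- .stage("cofiring", out_dir, {
      sid <- epochs$nonrhythmic$session_id
      span <- session_span(ds, sid)
      idx <- which(labels_df$session_id == sid & labels_df$retained)
      rows <- list()
      for (band in setdiff(names(epochs), "nonrhythmic")) {
        gam <- epochs[[band]]
        if (nrow(gam$intervals) == 0L ||
            nrow(epochs$nonrhythmic$intervals) == 0L) next
        pr <- 0L
        for (a in idx) for (b in idx) {
          if (a == b) next
          ka <- match(paste(labels_df$session_id[a], labels_df$cell_id[a]),
                      paste(ds$cells$session_id, ds$cells$cell_id))
          kb <- match(paste(labels_df$session_id[b], labels_df$cell_id[b]),
                      paste(ds$cells$session_id, ds$cells$cell_id))
          if (ds$cells$shank_id[ka] == ds$cells$shank_id[kb]) next
          if (pr >= max_pairs) break
          pr <- pr + 1L
          res <- cofiring_ratio(ds$spikes[[ka]], ds$spikes[[kb]],
                                epochs$nonrhythmic, gam,
                                config$ccg_bin_ms, config$ccg_half_window_ms,
                                config$cofire_half_window_ms)
          if (!res$defined) next
          nul <- shuffle_null(ds$spikes[[ka]], ds$spikes[[kb]],
                              epochs$nonrhythmic, gam, span,
                              n = config$shuffle_n,
                              range_s = config$shuffle_range_s,
                              seed = derive_seed(seed, 4L, pr),
                              bin_ms = config$ccg_bin_ms,
                              half_window_ms = config$ccg_half_window_ms,
                              cofire_half_window_ms = config$cofire_half_window_ms)
          rows[[length(rows) + 1L]] <- data.frame(
            session = sid,
            cell_a = labels_df$cell_id[a], cell_b = labels_df$cell_id[b],
            pop_a = labels_df$population[a], pop_b = labels_df$population[b],
            band = band, cfr = res$cfr, ctrl_mean = nul$mean,
            ctrl_p2_5 = nul$p2.5, ctrl_p97_5 = nul$p97.5,
            stringsAsFactors = FALSE)
        }
      }
      tab <- if (length(rows)) do.call(rbind, rows) else NULL
      gt <- if (!is.null(tab) && nrow(tab) >= 3L) {
        population_pair_assembly(tab)
      } else NULL
      list(tab = tab, gt = gt)
    })
    cfr_table <- cfr_out$tab
    group_tests <- cfr_out$gt
  }

  .stage("write_outputs", out_dir, {
    write.csv(labels_df, file.path(out_dir, "labels.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(grid = stab$grid,
           selected = stab$selected[c("by_mean", "by_mean_over_sd")]),
      file.path(out_dir, "stability.json"),
      dataframe = "columns", auto_unbox = TRUE, digits = NA)
    if (length(epochs)) {
      write_epochs_csv(epochs, file.path(out_dir, "epochs.csv"))
    }
    if (!is.null(cfr_table)) {
      write.csv(cfr_table, file.path(out_dir, "cfr_table.csv"),
                row.names = FALSE, quote = FALSE)
    }
    if (!is.null(group_tests)) {
      jsonlite::write_json(group_tests, file.path(out_dir, "group_tests.json"),
                           dataframe = "columns", auto_unbox = TRUE, digits = NA)
    }
    summary <- list(
      n_cells = n_cells(ds), n_cells_used = nrow(feats$cells),
      n_components = feats$m,
      selected_k = sel$k, selected_knn = sel$knn,
      n_retained = sum(sil$retained),
      populations = as.list(table(labels_df$population)),
      n_pairs_scored = if (is.null(cfr_table)) 0L else nrow(cfr_table))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  })

  invisible(list(features = feats, stability = stab, solution = solution,
                 silhouette = sil, profile = profile, labels = labels_df,
                 epochs = epochs, cfr_table = cfr_table,
                 group_tests = group_tests))
}
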