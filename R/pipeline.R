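#' Refine one caller VCF end to end
#'
#' Reads, refines (annotate, size-filter, deduplicate, PASS-filter) and
#' caller-tags a VCF, optionally writing the refined VCF and the per-step
#' removal-count TSV.
#'
#' @param vcf Input VCF path.
#' @param caller Caller label.
#' @param out_vcf,stats_out Optional output paths for the refined VCF and
#'   the per-step count TSV.
#' @inheritParams refine_calls
#' @return The refined SV tibble (with `stats` attribute).
#' @export
refine_vcf <- function(vcf, caller, out_vcf = NULL, stats_out = NULL,
                       min_size = 50, pass_only = TRUE, dedup_paired = TRUE) {
  raw <- read_caller_vcf(vcf, caller)
  refined <- refine_calls(raw, caller, min_size = min_size,
                          pass_only = pass_only, dedup_paired = dedup_paired)
  if (!is.null(out_vcf)) write_sv_vcf(refined, out_vcf)
  if (!is.null(stats_out)) readr::write_tsv(attr(refined, "stats"), stats_out)
  refined
}

#' Validate a table of published confusion counts
#'
#' Checks that every per-dataset row satisfies `fp = total - tp` and that
#' each combined row equals the sum of its per-dataset counts. Both checks
#' must hold before published metrics can serve as a regression fixture.
#'
#' @param per_dataset Tibble with columns `dataset`, `callset`, `svtype`,
#'   `total`, `tp`, `fp`, `fn`.
#' @param combined Optional tibble with the same count columns, one row per
#'   (callset, svtype), to audit against the per-dataset sums.
#' @return Invisibly `TRUE`; aborts with a message naming the first
#'   offending row otherwise.
#' @export
audit_counts <- function(per_dataset, combined = NULL) {
  if (any(per_dataset$tp < 0 | per_dataset$fp < 0 | per_dataset$fn < 0)) {
    abort("Counts must be non-negative.")
  }
  bad <- which(per_dataset$total != per_dataset$tp + per_dataset$fp)
  if (length(bad)) {
    r <- per_dataset[bad[1], ]
    abort(paste0("Count audit failed: total != TP + FP for ", r$dataset, " ",
                 r$callset, " ", r$svtype, "."))
  }
  if (!is.null(combined)) {
    sums <- per_dataset |>
      dplyr::distinct(.data$dataset, .data$callset, .data$svtype,
                      .keep_all = TRUE) |>
      dplyr::group_by(.data$callset, .data$svtype) |>
      dplyr::summarise(dplyr::across(c("total", "tp", "fp", "fn"), sum),
                       .groups = "drop")
    chk <- dplyr::inner_join(
      sums, combined, by = c("callset", "svtype"),
      suffix = c(".sum", ".combined")
    )
    if (nrow(chk) != nrow(combined)) {
      abort("Count audit failed: combined rows without per-dataset counts.")
    }
    for (col in c("total", "tp", "fp", "fn")) {
      bad <- which(chk[[paste0(col, ".sum")]] != chk[[paste0(col, ".combined")]])
      if (length(bad)) {
        r <- chk[bad[1], ]
        abort(paste0("Count audit failed: combined ", col, " for ", r$callset,
                     " ", r$svtype, " is not the sum of per-dataset counts."))
      }
    }
  }
  invisible(TRUE)
}

#' Published benchmark counts fixture
#'
#' TP/FP/FN counts reported by a published benchmark of six short-read SV
#' callers (and their three- and five-caller combination strategies) on the
#' GIAB HG002 truth set and three HGSVC2 genomes, as shipped with the
#' package. The `table` column distinguishes the two per-dataset tables
#' (single callers; combination strategies -- the DRAGEN rows appear in
#' both) from the combined micro-average table (`dataset == "combined"`).
#' Printed 2-decimal recall/precision/F1 are included for regression
#' comparison.
#'
#' @return A tibble with columns `table`, `dataset`, `callset`, `svtype`,
#'   `total`, `tp`, `fp`, `fn`, `recall`, `precision`, `f1`.
#' @export
published_benchmark_counts <- function() {
  path <- system.file("extdata", "published_benchmark_counts.tsv",
                      package = "svensemble", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Recompute metric tables from confusion counts alone
#'
#' Counts-only mode: takes (dataset, callset, svtype, tp, fp, fn) rows --
#' for example the shipped published counts -- audits them, and emits the
#' full per-dataset and combined metric tables. This lets printed benchmark
#' counts serve as an exact regression fixture for the metric formulas
#' without any genomic data.
#'
#' @param counts Data frame with columns `dataset`, `callset`, `svtype`,
#'   `tp`, `fp`, `fn` (and optionally `total`); rows duplicated across
#'   source tables are collapsed.
#' @param out_dir Optional directory for TSV output
#'   (see [evaluation_report()]).
#' @return List with `per_dataset` and `combined` metric tibbles.
#' @export
reproduce_metric_tables <- function(counts, out_dir = NULL) {
  counts <- tibble::as_tibble(counts)
  needed <- c("dataset", "callset", "svtype", "tp", "fp", "fn")
  if (!all(needed %in% names(counts))) {
    abort(paste0("`counts` must have columns: ", paste(needed, collapse = ", ")))
  }
  counts <- dplyr::distinct(counts, .data$dataset, .data$callset, .data$svtype,
                            .keep_all = TRUE)
  if (!"total" %in% names(counts)) {
    counts <- dplyr::mutate(counts, total = .data$tp + .data$fp)
  }
  audit_counts(counts)
  evaluation_report(
    dplyr::select(counts, "dataset", "callset", "svtype", "total",
                  "tp", "fp", "fn"),
    out_dir = out_dir
  )
}

#' Run the whole pipeline on synthetic data
#'
#' Simulates `n_datasets` truth sets and caller call sets, round-trips them
#' through VCF files, refines every caller VCF, merges each panel under
#' each strategy, benchmarks single callers and merged call sets against
#' the truth per dataset, and micro-averages across datasets. All outputs
#' (VCFs, per-dataset metric TSVs, combined TSV, concordance and
#' group-distance TSVs, JSON metrics blob) land under `out_dir`. Fully
#' deterministic under `seed`.
#'
#' @param out_dir Output directory.
#' @param n_datasets Number of simulated datasets.
#' @param cfg [sim_config()] template; each dataset re-seeds it from `seed`.
#' @param profiles Named list of caller profiles.
#' @param panels Named list of caller panels (default III and V presets).
#' @param strategies Subset of multiple_agreement / union / direct_merge.
#' @param window,min_support,min_size Pipeline thresholds (defaults 500 bp,
#'   2 callers, 50 bp).
#' @param svtypes SV types to evaluate.
#' @param seed Master integer seed.
#' @return Invisibly, a list with `counts`, `report` (per-dataset +
#'   combined tables), `concordance`, and `out_dir`.
#' @export
sv_run_all <- function(out_dir, n_datasets = 2, cfg = sim_config(),
                       profiles = default_caller_profiles(),
                       panels = list(III = caller_panel("III"),
                                     V = caller_panel("V")),
                       strategies = c("multiple_agreement", "union"),
                       window = 500, min_support = 2, min_size = 50,
                       svtypes = c("DEL", "INS"), seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panels <- purrr::map(panels, caller_panel)
  all_counts <- list()
  concordance <- list()
  distances <- list()

  for (d in seq_len(n_datasets)) {
    label <- paste0("sim", d)
    ds_dir <- file.path(out_dir, label)
    cfg_d <- cfg
    cfg_d$seed <- (as.integer(seed) * 131L + d) %% .Machine$integer.max
    sim <- simulate_study(cfg_d, profiles, ds_dir)

    truth <- annotate_sv(read_caller_vcf(sim$paths[["truth"]]))
    refined <- purrr::imap(sim$calls, function(cs, nm) {
      refine_vcf(file.path(ds_dir, paste0(nm, ".vcf")), caller = nm,
                 out_vcf = file.path(ds_dir, paste0(nm, ".refined.vcf")),
                 stats_out = file.path(ds_dir, paste0(nm, ".refine_stats.tsv")),
                 min_size = min_size)
    })

    callsets <- refined
    for (pnm in names(panels)) {
      grouped <- NULL
      for (st in strategies) {
        merged <- merge_callsets(refined, panel = panels[[pnm]], strategy = st,
                                 window = window, min_support = min_support)
        grouped <- attr(merged, "groups")
        mnm <- paste0(pnm, "-", sub("multiple_agreement", "agreement", st))
        callsets[[mnm]] <- merged
        write_sv_vcf(merged, file.path(ds_dir, paste0(mnm, ".vcf")),
                     contigs = cfg$contigs)
      }
      if (!is.null(grouped)) {
        cc <- dplyr::mutate(concordance_counts(grouped), panel = pnm,
                            dataset = label, .before = 1)
        concordance[[paste(label, pnm)]] <- cc
        readr::write_tsv(
          dplyr::select(cc, "subset", "count"),
          file.path(ds_dir, paste0("concordance_", pnm, ".tsv"))
        )
        distances[[paste(label, pnm)]] <- dplyr::mutate(
          group_distance_summary(grouped), panel = pnm, dataset = label,
          .before = 1
        )
      }
    }

    bench <- benchmark_callsets(callsets, truth, svtypes = svtypes,
                                window = window, dataset = label)
    all_counts[[label]] <- bench$counts
  }

  counts <- dplyr::bind_rows(all_counts)
  report <- evaluation_report(counts, out_dir = out_dir)
  if (length(distances)) {
    readr::write_tsv(dplyr::bind_rows(distances),
                     file.path(out_dir, "group_distances.tsv"))
  }
  jsonlite::write_json(
    list(counts = counts, combined = report$combined),
    file.path(out_dir, "metrics.json"),
    dataframe = "rows", digits = NA
  )
  invisible(list(counts = counts, report = report,
                 concordance = dplyr::bind_rows(concordance),
                 out_dir = out_dir))
}
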