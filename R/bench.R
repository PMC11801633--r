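#' Match a test call set against a truth set
#'
#' A truth variant and a test call are candidate matches when they lie on
#' the same contig, share the SV type, and their start positions differ by
#' at most `window` bp (inclusive). Candidates are assigned one-to-one,
#' greedily by increasing distance (ties by truth then test position), so
#' each truth variant and each test call is consumed at most once -- the
#' only reading under which `FP = |test| - TP` and `FN = |truth| - TP` are
#' both consistent. SV length plays no role in matching.
#'
#' @param test,truth Annotated SV tibbles.
#' @param svtype The single SV type under evaluation (`"DEL"` or `"INS"`).
#'   Both inputs must contain only records of this type; pre-filter with
#'   `dplyr::filter()` if needed.
#' @param window Matching window in bp (default 500).
#' @return A one-row tibble of class `sv_confusion` with columns `svtype`,
#'   `test_total`, `truth_total`, `tp`, `fp`, `fn`, and the matched pairs
#'   as attribute `pairs` (columns `truth_idx`, `test_idx`, `distance`).
#' @export
match_to_truth <- function(test, truth, svtype, window = 500) {
  assert_sv_tbl(test, "test")
  assert_sv_tbl(truth, "truth")
  for (nm in c("test", "truth")) {
    x <- get(nm)
    if (nrow(x) && any(x$svtype != svtype)) {
      abort(paste0("`", nm, "` contains records of other SV types than ",
                   svtype, "; evaluation treats one type at a time."))
    }
  }

  pairs <- candidate_pairs(truth, test, window)
  matched <- greedy_assign(pairs, nrow(truth), nrow(test))
  tp <- nrow(matched)
  out <- tibble::tibble(
    svtype = svtype,
    test_total = nrow(test),
    truth_total = nrow(truth),
    tp = tp,
    fp = nrow(test) - tp,
    fn = nrow(truth) - tp
  )
  attr(out, "pairs") <- matched
  class(out) <- c("sv_confusion", class(out))
  out
}

# All (truth, test) index pairs on one contig within the window.
candidate_pairs <- function(truth, test, window) {
  if (nrow(truth) == 0 || nrow(test) == 0) {
    return(tibble::tibble(truth_idx = integer(), test_idx = integer(),
                          distance = integer()))
  }
  truth_i <- tibble::tibble(contig = truth$contig, pos = truth$pos,
                            truth_idx = seq_len(nrow(truth)))
  test_i <- tibble::tibble(contig = test$contig, pos = test$pos,
                           test_idx = seq_len(nrow(test)))
  out <- vector("list", length(unique(truth_i$contig)))
  k <- 0
  for (ctg in intersect(unique(truth_i$contig), unique(test_i$contig))) {
    tr <- truth_i[truth_i$contig == ctg, ]
    te <- test_i[test_i$contig == ctg, ]
    ord <- order(te$pos)
    te_pos <- te$pos[ord]
    te_idx <- te$test_idx[ord]
    lo <- findInterval(tr$pos - window - 0.5, te_pos) + 1L
    hi <- findInterval(tr$pos + window + 0.5, te_pos)
    any_hit <- hi >= lo
    if (!any(any_hit)) next
    k <- k + 1
    reps <- pmax(hi - lo + 1L, 0L)
    ti <- rep(tr$truth_idx, reps)
    tp <- rep(tr$pos, reps)
    je <- unlist(purrr::map2(lo, hi, function(a, b) if (b >= a) a:b else integer()))
    out[[k]] <- tibble::tibble(
      truth_idx = ti,
      test_idx = te_idx[je],
      distance = abs(tp - te_pos[je])
    )
  }
  if (k == 0) {
    return(tibble::tibble(truth_idx = integer(), test_idx = integer(),
                          distance = integer()))
  }
  dplyr::bind_rows(out[seq_len(k)])
}

# One-to-one greedy assignment by increasing distance.
greedy_assign <- function(pairs, n_truth, n_test) {
  if (nrow(pairs) == 0) return(pairs)
  pairs <- pairs[order(pairs$distance, pairs$truth_idx, pairs$test_idx), ]
  truth_used <- logical(n_truth)
  test_used <- logical(n_test)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ti <- pairs$truth_idx[i]
    te <- pairs$test_idx[i]
    if (!truth_used[ti] && !test_used[te]) {
      truth_used[ti] <- TRUE
      test_used[te] <- TRUE
      keep[i] <- TRUE
    }
  }
  pairs[keep, ]
}

#' Restrict records to confident regions
#'
#' Keeps records whose start position (converted to 0-based) falls inside
#' any BED interval. Intended for confident-region truth sets; evaluation
#' does not restrict by default.
#'
#' @param records Annotated SV tibble.
#' @param regions Tibble from [read_bed()] (0-based half-open intervals).
#' @return Filtered tibble.
#' @export
restrict_to_regions <- function(records, regions) {
  assert_sv_tbl(records)
  keep <- vapply(seq_len(nrow(records)), function(i) {
    p0 <- records$pos[i] - 1L
    any(regions$contig == records$contig[i] &
          regions$start <= p0 & p0 < regions$end)
  }, logical(1))
  out <- records[keep, ]
  attr(out, "contig_order") <- attr(records, "contig_order")
  out
}

#' Compute precision, recall and F1 from confusion counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R); any 0/0 is defined as 0 so empty call sets score 0
#' rather than erroring. Vectorized over rows, so a whole table of counts
#' can be scored at once.
#'
#' @param counts Data frame with columns `tp`, `fp`, `fn` (one row per
#'   evaluation).
#' @return `counts` with `precision`, `recall`, `f1` columns appended
#'   (full precision; see [round_half_up()] for the 2-decimal display
#'   convention).
#' @export
compute_metrics <- function(counts) {
  if (!all(c("tp", "fp", "fn") %in% names(counts))) {
    abort("`counts` must have columns tp, fp, fn.")
  }
  if (any(counts$tp < 0 | counts$fp < 0 | counts$fn < 0)) {
    abort("Confusion counts must be non-negative.")
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  dplyr::mutate(
    tibble::as_tibble(counts),
    precision = safe_div(.data$tp, .data$tp + .data$fp),
    recall = safe_div(.data$tp, .data$tp + .data$fn),
    f1 = safe_div(2 * .data$precision * .data$recall,
                  .data$precision + .data$recall)
  )
}

#' Micro-averaged combined metrics across datasets
#'
#' Sums TP/FP/FN across datasets within each (call set, SV type) and
#' computes combined precision (cPr), recall (cRc) and F1 (cF1) from the
#' summed counts. A single dataset reproduces [compute_metrics()] exactly.
#'
#' @param counts Data frame with columns `tp`, `fp`, `fn` and any of the
#'   grouping columns `callset`, `svtype` (rows sharing a group are summed).
#' @return One row per group with `tp`, `fp`, `fn` sums and `precision`,
#'   `recall`, `f1` of the sums.
#' @export
combine_micro <- function(counts) {
  if (nrow(counts) == 0) abort("`counts` must contain at least one row.")
  if (any(counts$tp < 0 | counts$fp < 0 | counts$fn < 0)) {
    abort("Confusion counts must be non-negative.")
  }
  group_cols <- intersect(c("callset", "svtype"), names(counts))
  summed <- counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      n_datasets = dplyr::n(),
      total = sum(.data$tp + .data$fp),
      tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
      .groups = "drop"
    )
  compute_metrics(summed)
}

#' Benchmark call sets against a truth set
#'
#' Evaluates each call set against the truth for each SV type separately
#' and returns an `sv_benchmark` object holding the confusion counts and
#' metrics. Use [tidy()] for per-row metrics, [glance()] for micro-averaged
#' combined metrics, and [autoplot()] for a metrics plot.
#'
#' @param callsets Named list of SV tibbles (refined single-caller or
#'   merged call sets).
#' @param truth Truth SV tibble.
#' @param svtypes SV types to evaluate (default DEL and INS; the types
#'   truth sets provide benchmarks for).
#' @param window Matching window in bp (default 500).
#' @param dataset Dataset label recorded on every row.
#' @param regions Optional confident-region tibble from [read_bed()];
#'   when supplied, both truth and test records are restricted to it.
#' @return An `sv_benchmark` object.
#' @export
benchmark_callsets <- function(callsets, truth, svtypes = c("DEL", "INS"),
                               window = 500, dataset = "dataset1",
                               regions = NULL) {
  if (is.null(names(callsets)) || any(!nzchar(names(callsets)))) {
    abort("`callsets` must be a named list.")
  }
  if (!is.null(regions)) truth <- restrict_to_regions(truth, regions)
  counts <- purrr::map(names(callsets), function(nm) {
    cs <- callsets[[nm]]
    if (!is.null(regions)) cs <- restrict_to_regions(cs, regions)
    purrr::map(svtypes, function(ty) {
      conf <- match_to_truth(
        dplyr::filter(cs, .data$svtype == ty),
        dplyr::filter(truth, .data$svtype == ty),
        svtype = ty, window = window
      )
      dplyr::mutate(tibble::as_tibble(conf), dataset = dataset, callset = nm,
                    .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  structure(
    list(
      counts = dplyr::select(counts, "dataset", "callset", "svtype",
                             total = "test_total", "tp", "fp", "fn"),
      metrics = compute_metrics(
        dplyr::select(counts, "dataset", "callset", "svtype",
                      total = "test_total", "tp", "fp", "fn")
      ),
      window = window,
      svtypes = svtypes
    ),
    class = "sv_benchmark"
  )
}

#' @export
print.sv_benchmark <- function(x, ...) {
  cat("<sv_benchmark>", nrow(x$counts), "evaluations,",
      "window", x$window, "bp\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy an sv_benchmark: one row per (dataset, call set, SV type)
#'
#' @param x An `sv_benchmark` object.
#' @param ... Unused.
#' @return Tibble of counts with `precision`, `recall`, `f1`.
#' @method tidy sv_benchmark
#' @export
tidy.sv_benchmark <- function(x, ...) {
  x$metrics
}

#' Glance at an sv_benchmark: micro-averaged combined metrics
#'
#' @param x An `sv_benchmark` object.
#' @param ... Unused.
#' @return One row per (call set, SV type) with summed counts and combined
#'   precision/recall/F1.
#' @method glance sv_benchmark
#' @export
glance.sv_benchmark <- function(x, ...) {
  combine_micro(x$counts)
}

#' Plot benchmark metrics
#'
#' Bar chart of precision, recall and F1 per call set, faceted by SV type
#' (and dataset when several are present).
#'
#' @param object An `sv_benchmark` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sv_benchmark
#' @export
autoplot.sv_benchmark <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = factor(.data$metric,
                                  levels = c("recall", "precision", "f1")))
  p <- ggplot2::ggplot(long,
         ggplot2::aes(x = .data$callset, y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "score", fill = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (dplyr::n_distinct(long$dataset) > 1) {
    p + ggplot2::facet_grid(dataset ~ svtype)
  } else {
    p + ggplot2::facet_wrap(~svtype)
  }
}

#' Metric report tables
#'
#' Builds per-dataset report tables (rows = call sets; columns = total, TP,
#' FP, FN, recall, precision, F1, plus the 2-decimal display values) and a
#' combined micro-averaged table, optionally writing them as TSV files.
#' Row order is deterministic: the order of first appearance of each call
#' set, then SV type.
#'
#' @param counts Data frame with columns `dataset`, `callset`, `svtype`,
#'   `tp`, `fp`, `fn` (and optionally `total`).
#' @param out_dir Optional directory; when given, writes
#'   `metrics_<dataset>.tsv` per dataset and `metrics_combined.tsv`.
#' @return List with `per_dataset` (named list of tibbles) and `combined`.
#' @export
evaluation_report <- function(counts, out_dir = NULL) {
  counts <- tibble::as_tibble(counts)
  if (!"total" %in% names(counts)) {
    counts <- dplyr::mutate(counts, total = .data$tp + .data$fp)
  }
  callset_order <- unique(counts$callset)
  add_display <- function(m) {
    dplyr::mutate(
      m,
      recall_2dp = round_half_up(.data$recall, 2),
      precision_2dp = round_half_up(.data$precision, 2),
      f1_2dp = round_half_up(.data$f1, 2)
    )
  }
  per_dataset <- counts |>
    dplyr::group_split(.data$dataset) |>
    purrr::map(function(d) {
      compute_metrics(d) |>
        dplyr::arrange(match(.data$callset, callset_order), .data$svtype) |>
        add_display()
    })
  names(per_dataset) <- purrr::map_chr(per_dataset, ~ .x$dataset[1])

  combined <- combine_micro(counts) |>
    dplyr::arrange(match(.data$callset, callset_order), .data$svtype) |>
    add_display()

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    purrr::iwalk(per_dataset, function(tbl, nm) {
      readr::write_tsv(tbl, file.path(out_dir, paste0("metrics_", nm, ".tsv")))
    })
    readr::write_tsv(combined, file.path(out_dir, "metrics_combined.tsv"))
  }
  list(per_dataset = per_dataset, combined = combined)
}
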