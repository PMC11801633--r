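#' Caller panel presets
#'
#' The two ensembles evaluated throughout the package: the three-caller
#' panel `III` (Manta, DELLY, GRIDSS) and the five-caller panel `V`
#' (Manta, DELLY, GRIDSS, LUMPY, SvABA).
#'
#' @param panel `"III"`, `"V"`, or a character vector of caller labels used
#'   as-is.
#' @return Character vector of caller labels.
#' @export
caller_panel <- function(panel = "III") {
  if (length(panel) == 1 && panel %in% c("III", "V")) {
    return(switch(panel,
      III = c("Manta", "DELLY", "GRIDSS"),
      V = c("Manta", "DELLY", "GRIDSS", "LUMPY", "SvABA")
    ))
  }
  if (anyDuplicated(panel)) abort("Panel caller labels must be unique.")
  as.character(panel)
}

#' Group pooled multi-caller calls into neighbor groups
#'
#' Within each (contig, SV type), records are sorted by position (ties
#' broken by caller label then record ID, so grouping is independent of
#' input order) and swept left to right: the first record opens a group and
#' becomes its representative; each subsequent record joins the open group
#' iff its position is within `window` bp of the representative's position,
#' otherwise it opens a new group. This anchored sweep guarantees every
#' member lies within `window` bp of its group's representative (the
#' smallest-position member), which transitive chaining would not.
#'
#' @param pooled Refined, caller-tagged records pooled across a panel.
#' @param window Breakpoint distance threshold in bp (default 500).
#' @return The pooled tibble in sweep order with added columns `group_id`
#'   (globally unique integer), `rep_pos` (the group representative's
#'   position) and `is_representative`.
#' @export
group_neighbors <- function(pooled, window = 500) {
  assert_sv_tbl(pooled, "pooled")
  if (window < 0) abort("`window` must be >= 0.")
  if (nrow(pooled) == 0) {
    return(dplyr::mutate(pooled, group_id = integer(), rep_pos = integer(),
                         is_representative = logical()))
  }
  if (!"caller" %in% names(pooled) || anyNA(pooled$caller)) {
    abort("All pooled records must be caller-tagged before grouping.")
  }

  record_id <- pooled$record_id %||% as.character(seq_len(nrow(pooled)))
  out <- pooled |>
    dplyr::mutate(.rid = record_id) |>
    dplyr::arrange(.data$contig, .data$svtype, .data$pos, .data$caller, .data$.rid) |>
    dplyr::group_by(.data$contig, .data$svtype) |>
    dplyr::mutate(.local_gid = anchor_sweep(.data$pos, window)) |>
    dplyr::ungroup()

  key <- paste(out$contig, out$svtype, out$.local_gid, sep = "\r")
  out$group_id <- match(key, unique(key))
  out <- out |>
    dplyr::group_by(.data$group_id) |>
    dplyr::mutate(
      rep_pos = .data$pos[1],
      is_representative = dplyr::row_number() == 1
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".local_gid", -".rid")
  attr(out, "window") <- window
  attr(out, "contig_order") <- attr(pooled, "contig_order")
  out
}

# Anchored left-to-right sweep over sorted positions: a record joins the
# open group iff within `window` of the group's first (anchor) position.
anchor_sweep <- function(pos, window) {
  n <- length(pos)
  gid <- integer(n)
  anchor <- pos[1]
  g <- 1L
  gid[1] <- g
  if (n > 1) {
    for (i in 2:n) {
      if (pos[i] - anchor > window) {
        g <- g + 1L
        anchor <- pos[i]
      }
      gid[i] <- g
    }
  }
  gid
}

#' Summarize neighbor groups
#'
#' @param grouped Output of [group_neighbors()].
#' @return One row per group: `group_id`, `contig`, `svtype`, `rep_pos`,
#'   `n_members`, `supp` (distinct supporting callers) and `callers`
#'   (comma-joined sorted labels).
#' @export
summarize_groups <- function(grouped) {
  grouped |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      contig = .data$contig[1],
      svtype = .data$svtype[1],
      rep_pos = .data$rep_pos[1],
      n_members = dplyr::n(),
      supp = dplyr::n_distinct(.data$caller),
      callers = paste(sort(unique(.data$caller)), collapse = ","),
      .groups = "drop"
    )
}

#' Produce a merged call set from neighbor groups
#'
#' Under `multiple_agreement`, the representative of each group supported
#' by at least `min_support` distinct callers is emitted; under `union`,
#' every group's representative is emitted; under `direct_merge`, the
#' pooled records are emitted unmerged (groups are ignored). Representatives
#' carry the comma-joined supporting caller labels in `caller`, plus `supp`
#' and `group_size` columns.
#'
#' @param grouped Output of [group_neighbors()] (for `direct_merge`, the
#'   pooled records themselves may be passed).
#' @param strategy `"multiple_agreement"`, `"union"`, or `"direct_merge"`.
#' @param min_support Minimum distinct supporting callers for
#'   `multiple_agreement` (default 2).
#' @return Merged SV tibble sorted by (contig order, position).
#' @export
apply_strategy <- function(grouped, strategy = c("multiple_agreement", "union",
                                                 "direct_merge"),
                           min_support = 2) {
  if (!is.character(strategy) || !all(strategy %in%
      c("multiple_agreement", "union", "direct_merge"))) {
    abort(paste0("Unknown strategy: ", paste(strategy, collapse = ", ")))
  }
  strategy <- match.arg(strategy)
  contig_order <- attr(grouped, "contig_order")

  if (strategy == "direct_merge") {
    out <- grouped |>
      dplyr::arrange(contig_rank(.data$contig, contig_order), .data$pos)
    return(out)
  }

  if (strategy == "multiple_agreement" && min_support < 2) {
    abort("`min_support` must be >= 2 for the multiple-agreement strategy.")
  }
  if (!"group_id" %in% names(grouped)) {
    abort("`grouped` must come from group_neighbors() for this strategy.")
  }

  reps <- grouped |>
    dplyr::group_by(.data$group_id) |>
    dplyr::mutate(
      supp = dplyr::n_distinct(.data$caller),
      group_size = dplyr::n(),
      caller = paste(sort(unique(.data$caller)), collapse = ",")
    ) |>
    dplyr::filter(.data$is_representative) |>
    dplyr::ungroup()

  if (strategy == "multiple_agreement") {
    reps <- dplyr::filter(reps, .data$supp >= min_support)
  }
  out <- reps |>
    dplyr::arrange(contig_rank(.data$contig, contig_order), .data$pos) |>
    dplyr::select(-"group_id", -"rep_pos", -"is_representative")
  attr(out, "contig_order") <- contig_order
  out
}

#' Pool, group and merge a panel of refined call sets
#'
#' Convenience wrapper: pools the panel's refined call sets, forms neighbor
#' groups, and applies a combination strategy.
#'
#' @param callsets Named list of refined, caller-tagged SV tibbles, or a
#'   single pooled tibble with a `caller` column.
#' @param panel Panel preset or caller labels (see [caller_panel()]);
#'   callsets are subset to the panel. Every panel label must be present.
#' @param strategy Combination strategy (see [apply_strategy()]).
#' @param window Breakpoint distance threshold in bp (default 500).
#' @param min_support Minimum supporting callers for multiple agreement.
#' @return Merged SV tibble; the grouped tibble is attached as attribute
#'   `groups`.
#' @export
merge_callsets <- function(callsets, panel = "III",
                           strategy = "multiple_agreement",
                           window = 500, min_support = 2) {
  panel <- caller_panel(panel)
  if (is.data.frame(callsets)) {
    pooled <- callsets
  } else {
    missing <- setdiff(panel, names(callsets))
    if (length(missing)) {
      abort(paste0("Panel caller(s) not among provided call sets: ",
                   paste(missing, collapse = ", ")))
    }
    contig_order <- attr(callsets[[panel[1]]], "contig_order")
    pooled <- dplyr::bind_rows(callsets[panel])
    attr(pooled, "contig_order") <- contig_order
  }
  co <- attr(pooled, "contig_order")
  pooled <- dplyr::filter(pooled, .data$caller %in% panel)
  attr(pooled, "contig_order") <- co

  grouped <- group_neighbors(pooled, window)
  merged <- if (strategy == "direct_merge") {
    apply_strategy(pooled, strategy, min_support)
  } else {
    apply_strategy(grouped, strategy, min_support)
  }
  attr(merged, "groups") <- grouped
  merged
}

#' Concordance counts over caller subsets
#'
#' Tabulates, for each exact subset of supporting callers, how many neighbor
#' groups were supported by exactly that subset -- the counts underlying a
#' Venn diagram of caller agreement. Subset counts sum to the number of
#' groups.
#'
#' @param grouped Output of [group_neighbors()].
#' @return A tibble with columns `subset` (comma-joined sorted caller
#'   labels) and `count`, sorted by decreasing count then subset.
#' @export
concordance_counts <- function(grouped) {
  summarize_groups(grouped) |>
    dplyr::count(subset = .data$callers, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$subset)
}

#' Distances between group members and their representative
#'
#' Collects `pos - rep_pos` over all non-representative members and
#' summarizes them (median, IQR, max; quartile type 7). With no multi-member
#' groups the summary values are `NA`.
#'
#' @param grouped Output of [group_neighbors()].
#' @return A one-row tibble: `n_distances`, `median`, `iqr`, `max`.
#' @export
group_distance_summary <- function(grouped) {
  d <- grouped$pos[!grouped$is_representative] -
    grouped$rep_pos[!grouped$is_representative]
  if (length(d) == 0) {
    return(tibble::tibble(n_distances = 0L, median = NA_real_,
                          iqr = NA_real_, max = NA_real_))
  }
  tibble::tibble(
    n_distances = length(d),
    median = median(d),
    iqr = unname(diff(quantile(d, c(0.25, 0.75)))),
    max = max(d)
  )
}
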