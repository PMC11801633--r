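#' Simulation configuration for synthetic truth sets
#'
#' Defaults mirror the structure of curated short-read SV benchmarks:
#' deletion and insertion truth variants with sizes log-uniform on
#' 50 bp--10 kb, and a minimum inter-variant spacing of 1001 bp (curated
#' benchmarks exclude supported variants within 1000 bp of each other as
#' potentially complex), which also keeps evaluation against a 500 bp
#' matching window unambiguous.
#'
#' @param contigs Named numeric vector of contig lengths in bp.
#' @param n_truth Named counts of truth variants per SV type.
#' @param size_range Length-2 vector; sizes are drawn log-uniformly on this
#'   range (bp).
#' @param min_spacing Minimum distance between any two truth variants (bp).
#' @param seed Integer seed; all simulation randomness derives from it.
#' @return An `sv_sim_config` list.
#' @export
sim_config <- function(contigs = c(chr1 = 1.2e8, chr2 = 1.0e8),
                       n_truth = c(DEL = 2000, INS = 2000),
                       size_range = c(50, 10000),
                       min_spacing = 1001,
                       seed = 1L) {
  if (is.null(names(contigs)) || any(!nzchar(names(contigs)))) {
    abort("`contigs` must be a named vector of lengths.")
  }
  if (any(size_range < 50)) abort("Simulated SV sizes must be >= 50 bp.")
  structure(
    list(contigs = contigs, n_truth = n_truth, size_range = size_range,
         min_spacing = min_spacing, seed = as.integer(seed)),
    class = "sv_sim_config"
  )
}

#' Caller profile for the call-set simulator
#'
#' Describes one caller's behavior: per-type recall, expected
#' false-positive load (Poisson mean per type), breakpoint jitter (a
#' discretized double-geometric offset with mean magnitude `jitter` bp,
#' clamped to 500 bp so a detected call always stays within the default
#' matching window of its truth variant), and output-dialect quirks the
#' refinement stage must absorb: paired breakend records, a load of sub-50
#' bp records, a load of non-PASS records, and whether insertions are
#' detected at all.
#'
#' @param name Caller label.
#' @param recall Named probabilities per SV type (e.g.
#'   `c(DEL = 0.55, INS = 0.19)`).
#' @param fp_count Named Poisson means of false positives per SV type.
#' @param jitter Mean breakpoint offset magnitude in bp (0 = exact).
#' @param emits_paired_records Write DEL/DUP/INV as two BND mate lines.
#' @param sub50_fraction Extra sub-50 bp records, as a fraction of the
#'   caller's emitted calls.
#' @param nonpass_fraction Extra non-PASS (`FILTER=q5`) records, likewise.
#' @param detects_ins If `FALSE`, insertion truth variants are never
#'   emitted (recall 0 for INS).
#' @return An `sv_caller_profile` list.
#' @export
caller_profile <- function(name, recall, fp_count = c(DEL = 0, INS = 0),
                           jitter = 0, emits_paired_records = FALSE,
                           sub50_fraction = 0, nonpass_fraction = 0,
                           detects_ins = TRUE) {
  if (any(recall < 0 | recall > 1)) abort("`recall` must be in [0, 1].")
  if (any(c(sub50_fraction, nonpass_fraction) < 0) ||
      any(c(sub50_fraction, nonpass_fraction) > 1)) {
    abort("Dialect fractions must be in [0, 1].")
  }
  structure(
    list(name = name, recall = recall, fp_count = fp_count, jitter = jitter,
         emits_paired_records = emits_paired_records,
         sub50_fraction = sub50_fraction,
         nonpass_fraction = nonpass_fraction,
         detects_ins = detects_ins),
    class = "sv_caller_profile"
  )
}

#' Default caller profiles
#'
#' Five profiles whose DEL/INS recalls approximate the behavior of widely
#' used short-read SV callers on a well-characterized human benchmark
#' genome: Manta-like (recall DEL 0.55 / INS 0.19), DELLY-like (0.48 /
#' 0.02), GRIDSS-like (0.42 / 0.01, many sub-50 bp records, paired
#' breakends), LUMPY-like (0.12, no insertions, paired breakends) and
#' SvABA-like (0.28, no insertions, paired breakends). False-positive
#' loads are scaled to the default 2000-variant truth sets so each
#' profile's precision is in the range observed for its namesake.
#'
#' @return Named list of [caller_profile()] objects.
#' @export
default_caller_profiles <- function() {
  profiles <- list(
    caller_profile("Manta", recall = c(DEL = 0.55, INS = 0.19),
                   fp_count = c(DEL = 344, INS = 113), jitter = 5,
                   nonpass_fraction = 0.05),
    caller_profile("DELLY", recall = c(DEL = 0.48, INS = 0.02),
                   fp_count = c(DEL = 557, INS = 4), jitter = 10,
                   nonpass_fraction = 0.05),
    caller_profile("GRIDSS", recall = c(DEL = 0.42, INS = 0.01),
                   fp_count = c(DEL = 140, INS = 1), jitter = 10,
                   emits_paired_records = TRUE, sub50_fraction = 0.3,
                   nonpass_fraction = 0.05),
    caller_profile("LUMPY", recall = c(DEL = 0.12, INS = 0),
                   fp_count = c(DEL = 315, INS = 0), jitter = 20,
                   emits_paired_records = TRUE, detects_ins = FALSE),
    caller_profile("SvABA", recall = c(DEL = 0.28, INS = 0),
                   fp_count = c(DEL = 141, INS = 0), jitter = 10,
                   emits_paired_records = TRUE, detects_ins = FALSE,
                   nonpass_fraction = 0.05)
  )
  setNames(profiles, purrr::map_chr(profiles, "name"))
}

#' Simulate a truth set
#'
#' Positions are drawn uniformly per contig under the minimum-spacing
#' constraint (via the order-statistics construction: uniform draws on the
#' shrunken interval plus cumulative spacing offsets), types are assigned
#' by random permutation, and sizes are log-uniform on `size_range`.
#' Deterministic under `cfg$seed`.
#'
#' @param cfg An [sim_config()] object.
#' @return An annotated SV tibble of truth records (caller untagged) with
#'   the contig lengths attached as attribute `contigs`.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sv_sim_config"))
  n_total <- sum(cfg$n_truth)
  spacing <- cfg$min_spacing
  if (n_total * spacing > sum(cfg$contigs)) {
    abort(paste0("Cannot place ", n_total, " truth variants at spacing ",
                 spacing, " bp on ", format(sum(cfg$contigs), scientific = FALSE),
                 " bp of contig space."))
  }

  # Deterministic proportional allocation of variant counts to contigs.
  alloc <- floor(n_total * cfg$contigs / sum(cfg$contigs))
  rem <- n_total - sum(alloc)
  if (rem > 0) {
    frac <- n_total * cfg$contigs / sum(cfg$contigs) - alloc
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    alloc[bump] <- alloc[bump] + 1
  }
  infeasible <- alloc > 0 & (alloc - 1) * spacing + 1 > cfg$contigs
  if (any(infeasible)) {
    abort(paste0("Contig ", names(cfg$contigs)[which(infeasible)[1]],
                 " too short for ", alloc[which(infeasible)[1]],
                 " variants at spacing ", spacing, " bp."))
  }

  withr::with_seed(cfg$seed, {
    pos <- purrr::imap(as.list(alloc), function(n, ctg) {
      if (n == 0) return(integer())
      L <- cfg$contigs[[ctg]]
      u <- sort(runif(n, 1, L - (n - 1) * spacing))
      floor(u) + (seq_len(n) - 1L) * spacing
    })
    contig <- rep(names(alloc), lengths(pos))
    pos <- unlist(pos, use.names = FALSE)
    types <- sample(rep(names(cfg$n_truth), cfg$n_truth))
    sizes <- round(exp(runif(n_total, log(cfg$size_range[1]),
                             log(cfg$size_range[2]))))
    sizes <- pmax(sizes, 50L)
  })

  out <- tibble::tibble(
    contig = contig,
    pos = as.integer(pos),
    end = as.integer(ifelse(types == "DEL", pos + sizes, pos)),
    svtype = types,
    svlen = as.integer(sizes),
    filter = "PASS",
    caller = NA_character_,
    record_id = sprintf("truth_%05d", seq_len(n_total)),
    mate_id = NA_character_,
    mate_contig = NA_character_,
    extra_info = NA_character_
  )
  attr(out, "contigs") <- cfg$contigs
  attr(out, "contig_order") <- names(cfg$contigs)
  out
}

# Discretized double-geometric jitter: sign x geometric magnitude with mean
# `scale`, clamped to +/- 500 bp (the default matching window).
draw_jitter <- function(n, scale, clamp = 500) {
  if (scale <= 0 || n == 0) return(integer(n))
  mag <- pmin(rgeom(n, prob = 1 / (1 + scale)), clamp)
  sgn <- sample(c(-1L, 1L), n, replace = TRUE)
  as.integer(sgn * mag)
}

# Uniform positions at least `min_dist` bp from every truth position on the
# same contig (rejection sampling).
draw_far_positions <- function(n, contigs, truth, min_dist = 1000) {
  if (n == 0) {
    return(tibble::tibble(contig = character(), pos = integer()))
  }
  truth_by_ctg <- split(truth$pos, truth$contig)
  got <- 0
  acc_ctg <- character(n)
  acc_pos <- integer(n)
  while (got < n) {
    m <- (n - got) * 2 + 10
    ctg <- sample(names(contigs), m, replace = TRUE,
                  prob = contigs / sum(contigs))
    pos <- floor(runif(m, 1, contigs[ctg])) + 0
    ok <- vapply(seq_len(m), function(i) {
      tp <- truth_by_ctg[[ctg[i]]]
      is.null(tp) || min(abs(tp - pos[i])) > min_dist
    }, logical(1))
    take <- min(sum(ok), n - got)
    if (take > 0) {
      idx <- which(ok)[seq_len(take)]
      acc_ctg[got + seq_len(take)] <- ctg[idx]
      acc_pos[got + seq_len(take)] <- as.integer(pos[idx])
      got <- got + take
    }
  }
  tibble::tibble(contig = acc_ctg, pos = acc_pos)
}

#' Simulate one caller's call set from a truth set
#'
#' Each truth variant of type T is emitted with probability `recall[T]`
#' (never, for insertions, when the profile does not detect them), at the
#' truth position plus a jitter draw. False positives are drawn per type
#' with Poisson counts around `fp_count[T]` and placed more than 1000 bp
#' (window + maximum jitter) from every truth variant, so they can never
#' match truth after refinement. Dialect noise -- sub-50 bp records and
#' non-PASS records, also placed far from truth -- exercises the size and
#' PASS filters without perturbing recall or FP recovery. Deterministic
#' under `seed`.
#'
#' @param truth Truth tibble from [simulate_truth()].
#' @param profile An [caller_profile()] object.
#' @param seed Integer seed.
#' @return An annotated SV tibble of simulated calls (caller column set to
#'   the profile name); attribute `dialect` is `"paired"` or `"plain"` for
#'   [write_sv_vcf()].
#' @export
simulate_caller_calls <- function(truth, profile, seed) {
  stopifnot(inherits(profile, "sv_caller_profile"))
  contigs <- attr(truth, "contigs")
  if (is.null(contigs)) abort("`truth` must carry a `contigs` attribute.")

  withr::with_seed(as.integer(seed), {
    eff_recall <- unname(dplyr::coalesce(profile$recall[truth$svtype], 0))
    eff_recall[truth$svtype == "INS" & !profile$detects_ins] <- 0
    detected <- runif(nrow(truth)) < eff_recall

    det <- truth[detected, ]
    jit <- draw_jitter(nrow(det), profile$jitter)
    det$pos <- pmax(1L, pmin(det$pos + jit, as.integer(contigs[det$contig])))
    det$end <- as.integer(ifelse(det$svtype == "DEL", det$pos + det$svlen, det$pos))

    fp <- purrr::imap(as.list(profile$fp_count), function(mu, ty) {
      n_fp <- rpois(1, mu)
      if (ty == "INS" && !profile$detects_ins) n_fp <- 0
      loc <- draw_far_positions(n_fp, contigs, truth)
      sizes <- pmax(round(exp(runif(n_fp, log(50), log(10000)))), 50L)
      tibble::tibble(
        contig = loc$contig, pos = loc$pos,
        end = as.integer(if (ty == "DEL") loc$pos + sizes else loc$pos),
        svtype = ty, svlen = as.integer(sizes), filter = "PASS"
      )
    }) |> dplyr::bind_rows()

    n_base <- nrow(det) + nrow(fp)
    n_sub50 <- round(profile$sub50_fraction * n_base)
    n_nonpass <- round(profile$nonpass_fraction * n_base)
    sub50 <- {
      loc <- draw_far_positions(n_sub50, contigs, truth)
      sizes <- if (n_sub50) sample(10:49, n_sub50, replace = TRUE) else integer()
      tibble::tibble(
        contig = loc$contig, pos = loc$pos, end = loc$pos + sizes,
        svtype = if (n_sub50) sample(c("DEL", "INS"), n_sub50, replace = TRUE)
                 else character(),
        svlen = as.integer(sizes), filter = "PASS"
      )
    }
    nonpass <- {
      loc <- draw_far_positions(n_nonpass, contigs, truth)
      sizes <- pmax(round(exp(runif(n_nonpass, log(50), log(10000)))), 50L)
      tibble::tibble(
        contig = loc$contig, pos = loc$pos, end = loc$pos + sizes,
        svtype = if (n_nonpass) sample(c("DEL", "INS"), n_nonpass, replace = TRUE)
                 else character(),
        svlen = as.integer(sizes), filter = "q5"
      )
    }
  })

  calls <- dplyr::bind_rows(
    dplyr::select(det, "contig", "pos", "end", "svtype", "svlen", "filter"),
    fp, sub50, nonpass
  )
  calls <- calls[order(contig_rank(calls$contig, names(contigs)), calls$pos), ]
  out <- dplyr::mutate(
    calls,
    end = as.integer(.data$end),
    caller = profile$name,
    record_id = sprintf("%s_%06d", tolower(profile$name),
                        seq_len(nrow(calls))),
    mate_id = NA_character_, mate_contig = NA_character_,
    extra_info = NA_character_
  )
  attr(out, "contigs") <- contigs
  attr(out, "contig_order") <- names(contigs)
  attr(out, "dialect") <- if (profile$emits_paired_records) "paired" else "plain"
  out
}

#' Simulate a complete study: truth plus one VCF per caller profile
#'
#' Writes `truth.vcf`, one `<caller>.vcf` per profile (in that caller's
#' dialect) and a `manifest.tsv` (caller, file, n_records, seed, dialect)
#' into `dir`. Per-caller seeds are derived deterministically from
#' `cfg$seed`.
#'
#' @param cfg An [sim_config()] object.
#' @param profiles Named list of caller profiles
#'   (default [default_caller_profiles()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `truth` (tibble), `calls` (named list of
#'   tibbles), `paths` and `manifest`.
#' @export
simulate_study <- function(cfg, profiles = default_caller_profiles(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_truth(cfg)
  truth_path <- file.path(dir, "truth.vcf")
  write_sv_vcf(truth, truth_path, contigs = cfg$contigs)

  calls <- list()
  rows <- list()
  for (k in seq_along(profiles)) {
    pr <- profiles[[k]]
    seed_k <- (cfg$seed * 1009L + k) %% .Machine$integer.max
    cs <- simulate_caller_calls(truth, pr, seed = seed_k)
    path <- file.path(dir, paste0(pr$name, ".vcf"))
    write_sv_vcf(cs, path, dialect = attr(cs, "dialect"), contigs = cfg$contigs)
    calls[[pr$name]] <- cs
    rows[[k]] <- tibble::tibble(
      caller = pr$name, file = basename(path), n_records = nrow(cs),
      seed = seed_k, dialect = attr(cs, "dialect")
    )
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(list(
    truth = truth, calls = calls,
    paths = c(truth = truth_path,
              setNames(file.path(dir, paste0(names(calls), ".vcf")),
                       names(calls))),
    manifest = manifest
  ))
}
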