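#' Built-in empirical missing-data patterns
#'
#' The four within-window missingness patterns used by the semisimulation,
#' each describing the gaps observed in a genuinely sparse 5-minute window
#' at a nominal missingness level:
#'
#' * **60%**: one burst covering the first 3.15 min of the window
#'   (\[0, 189\] s) -- non-wear at the window start.
#' * **35%**: one burst between minute 1.00 and minute 2.75
#'   (\[60, 165\] s).
#' * **20%**: 0.80 min (48 s) of data scattered in 1--2 s dropouts.
#' * **10%**: 0.63 min (37.8 s) scattered the same way.
#'
#' Scattered gaps have lengths uniform on \[1, 2\] s (the final gap trimmed
#' so the total is exact), placed sequentially at uniform random offsets
#' with overlaps rejected; placement is deterministic under `seed`. Patterns
#' are defined by removed *duration*, not an exact point percentage: the
#' level labels are nominal, and removed-point fractions on real beat
#' spacings differ slightly (the 60% burst covers 63% of the window).
#'
#' @param seed Integer seed for the scattered-gap placement.
#' @return Named list (`"10"`, `"20"`, `"35"`, `"60"`) of `gap_pattern`
#'   objects, each a list with `level`, `kind` (`"burst"`/`"scatter"`) and
#'   `gaps` (tibble of `start_s`, `end_s` offsets from the window start).
#' @export
#' @examples
#' p <- builtin_patterns(seed = 7)
#' pattern_duration_min(p[["60"]]) # 3.15
builtin_patterns <- function(seed = 1L) {
  burst <- function(level, from_s, to_s) {
    structure(list(level = level, kind = "burst",
                   gaps = tibble::tibble(start_s = from_s, end_s = to_s)),
              class = "gap_pattern")
  }
  scatter <- function(level, total_s, seed) {
    gaps <- withr::with_seed(seed, scatter_gaps(total_s))
    structure(list(level = level, kind = "scatter", gaps = gaps),
              class = "gap_pattern")
  }
  list(
    "10" = scatter(10, 37.8, seed),
    "20" = scatter(20, 48.0, seed + 1L),
    "35" = burst(35, 60, 165),
    "60" = burst(60, 0, 189)
  )
}

# draw non-overlapping 1-2 s gaps totalling exactly total_s within [0, 300] s
scatter_gaps <- function(total_s, window_s = 300, min_sep = 0.5) {
  lens <- numeric()
  remaining <- total_s
  while (remaining > 2) {
    # keep the eventual final gap inside [1, 2]
    hi <- min(2, remaining - 1)
    lens <- c(lens, runif(1, 1, hi))
    remaining <- total_s - sum(lens)
  }
  lens <- c(lens, remaining)
  starts <- numeric(length(lens))
  placed <- matrix(numeric(0), ncol = 2)
  for (i in seq_along(lens)) {
    repeat {
      s <- runif(1, 0, window_s - lens[i])
      e <- s + lens[i]
      if (nrow(placed) == 0 ||
          all(e + min_sep <= placed[, 1] | s - min_sep >= placed[, 2])) {
        placed <- rbind(placed, c(s, e))
        starts[i] <- s
        break
      }
    }
  }
  o <- order(starts)
  tibble::tibble(start_s = starts[o], end_s = starts[o] + lens[o])
}

#' Total missing duration of a gap pattern, minutes
#'
#' @param pattern A `gap_pattern` from [builtin_patterns()].
#' @return Scalar: summed gap length in minutes.
#' @export
pattern_duration_min <- function(pattern) {
  sum(pattern$gaps$end_s - pattern$gaps$start_s) / 60
}

#' Apply a missingness pattern to windows
#'
#' Removes every sample whose offset from the window start falls inside one
#' of the pattern's gap intervals (half-open `[start, end)`); all other
#' samples are retained bit-identically. `n_points` and
#' `expected_fraction_pct` are recomputed and the achieved missing fraction
#' recorded. Gap/usability columns from a previous [find_gaps()] pass are
#' dropped, since they no longer describe the degraded samples.
#'
#' @param windows Window tibble from [segment_windows()].
#' @param pattern A `gap_pattern`.
#' @return Degraded window tibble with added `level` and
#'   `achieved_missingness` columns.
#' @export
apply_pattern <- function(windows, pattern) {
  stopifnot(inherits(pattern, "gap_pattern"))
  n_before <- purrr::map_int(windows$samples, nrow)
  kept <- purrr::map2(windows$samples, windows$window_start_ms, function(s, w0) {
    off <- (s$timestamp_ms - w0) / 1000
    drop <- rep(FALSE, nrow(s))
    for (i in seq_len(nrow(pattern$gaps))) {
      drop <- drop | (off >= pattern$gaps$start_s[i] & off < pattern$gaps$end_s[i])
    }
    s[!drop, , drop = FALSE]
  })
  windows |>
    dplyr::select(-dplyr::any_of(c("gaps", "n_gaps", "usable_start_ms",
                                   "usable_end_ms", "usable"))) |>
    dplyr::mutate(
      samples = kept,
      n_points = purrr::map_int(kept, nrow),
      expected_fraction_pct = expected_data_fraction(.data$n_points),
      level = pattern$level,
      achieved_missingness = ifelse(n_before > 0, 1 - .data$n_points / n_before, 0)
    )
}

#' Degrade a reference window set at one or more nominal levels
#'
#' Applies the built-in pattern for each requested level to every window --
#' one sampled pattern instance per level, reused across all windows, as in
#' a semisimulation that transplants an observed sparse-window gap layout
#' onto every reference window. Optionally the scattered patterns can be
#' re-randomised per window for sensitivity analysis.
#'
#' @param windows Reference window tibble.
#' @param levels Subset of `c(10, 20, 35, 60)`.
#' @param seed Integer seed for scattered-gap placement.
#' @param rerandomize_scatter If `TRUE`, draw a fresh scatter layout for each
#'   window (default `FALSE`).
#' @return Window tibble stacking all levels, with `level` and
#'   `achieved_missingness` columns.
#' @export
degrade_dataset <- function(windows, levels = c(10, 20, 35, 60), seed = 1L,
                            rerandomize_scatter = FALSE) {
  bad <- setdiff(levels, c(10, 20, 35, 60))
  if (length(bad)) {
    abort(sprintf("Unknown degradation level(s) %s; valid levels are 10, 20, 35, 60.",
                  paste(bad, collapse = ", ")))
  }
  pats <- builtin_patterns(seed)
  purrr::map_dfr(as.character(levels), function(lv) {
    pat <- pats[[lv]]
    if (rerandomize_scatter && pat$kind == "scatter") {
      purrr::map_dfr(seq_len(nrow(windows)), function(i) {
        pat_i <- builtin_patterns(seed + i)[[lv]]
        apply_pattern(windows[i, ], pat_i)
      })
    } else {
      apply_pattern(windows, pat)
    }
  })
}

#' Serialise gap patterns to JSON
#'
#' @param patterns A `gap_pattern` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patterns <- function(patterns, path) {
  if (inherits(patterns, "gap_pattern")) patterns <- list(patterns)
  out <- lapply(patterns, function(p) {
    list(level = p$level, kind = p$kind,
         gaps = mapply(c, p$gaps$start_s, p$gaps$end_s, SIMPLIFY = FALSE))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
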