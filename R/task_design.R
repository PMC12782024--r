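# Stimulus design constants: 7 durations spanning the 2 s / 5 s references,
# and the 2x2 semantic-category x valence condition grid.

#' Stimulus durations of the bisection task (seconds)
#'
#' Seven durations from 2 to 5 s in 0.5 s steps; 2 s and 5 s double as the
#' short and long reference intervals learned in training.
#' @return Numeric vector of length 7.
#' @export
bisection_durations <- function() seq(2, 5, by = 0.5)

#' Reference durations (short, long) in seconds
#' @return Named numeric vector `c(short = 2, long = 5)`.
#' @export
reference_durations <- function() c(short = 2, long = 5)

#' The four sound conditions
#'
#' Full crossing of semantic category (environmental, human) with valence
#' (pleasant, unpleasant).
#' @return A data.frame with columns `semantic_category`, `valence` and a
#'   combined `condition` label, 4 rows.
#' @export
condition_grid <- function() {
  g <- expand.grid(
    semantic_category = c("environmental", "human"),
    valence = c("pleasant", "unpleasant"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g$condition <- paste(g$semantic_category, g$valence, sep = "-")
  g[order(g$condition), , drop = FALSE]
}

#' Default stimulus exemplars
#'
#' Eight sound identifiers, two per condition, following the naturalistic
#' stimulus set (running water and machine noises; laughter and crying).
#' @return Named character vector of length 8; names are condition labels.
#' @export
default_exemplars <- function() {
  c("environmental-pleasant" = "brook",
    "environmental-pleasant" = "river",
    "environmental-unpleasant" = "angle_grinder",
    "environmental-unpleasant" = "car_horn",
    "human-pleasant" = "laughter_female",
    "human-pleasant" = "laughter_male",
    "human-unpleasant" = "crying_female",
    "human-unpleasant" = "crying_male")
}

check_exemplars <- function(exemplars) {
  if (length(exemplars) != 8L || is.null(names(exemplars))) {
    stop("design error: exactly 8 named exemplars (2 per condition) required",
         call. = FALSE)
  }
  tab <- table(names(exemplars))
  want <- condition_grid()$condition
  if (!setequal(names(tab), want) || any(tab != 2L)) {
    stop("design error: exemplars must cover each of the 4 conditions exactly twice",
         call. = FALSE)
  }
  if (anyDuplicated(exemplars)) {
    stop("design error: exemplar identifiers must be unique", call. = FALSE)
  }
  invisible(exemplars)
}

split_condition <- function(condition) {
  parts <- strsplit(condition, "-", fixed = TRUE)
  data.frame(
    condition_category = vapply(parts, `[`, "", 1L),
    condition_valence = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
}

new_schedule <- function(trials, phase, seed) {
  structure(trials, class = c("bisect_schedule", "data.frame"),
            phase = phase, seed = seed)
}

#' @export
print.bisect_schedule <- function(x, ...) {
  cat(sprintf("<bisect_schedule: %s phase, %d trials, %d block(s), seed %d>\n",
              attr(x, "phase"), nrow(x), length(unique(x$block)),
              attr(x, "seed")))
  print.data.frame(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat(sprintf("... %d more trials\n", nrow(x) - 8L))
  invisible(x)
}

#' Build the training-phase schedule
#'
#' Sixteen trials in which each of the 8 exemplars is presented once at the
#' short (2 s) and once at the long (5 s) reference duration, in seeded
#' random order.
#'
#' @param exemplars Named character vector of 8 sound identifiers, two per
#'   condition (see [default_exemplars()]).
#' @param seed Integer seed controlling the presentation order and ITIs.
#' @return A `bisect_schedule` data.frame with columns `phase`, `block`,
#'   `trial`, `condition_category`, `condition_valence`, `exemplar`,
#'   `duration_s`, `iti_s`.
#' @export
build_training_schedule <- function(exemplars = default_exemplars(), seed = 1L) {
  check_exemplars(exemplars)
  refs <- reference_durations()
  base <- data.frame(
    condition = rep(names(exemplars), times = 2L),
    exemplar = rep(unname(exemplars), times = 2L),
    duration_s = rep(unname(refs), each = 8L),
    stringsAsFactors = FALSE
  )
  ord <- with_temp_seed(seed, sample.int(nrow(base)))
  base <- base[ord, , drop = FALSE]
  iti <- with_temp_seed(seed + 1L, stats::runif(nrow(base), 1, 3))
  trials <- cbind(
    data.frame(phase = "training", block = 0L, trial = seq_len(nrow(base))),
    split_condition(base$condition),
    data.frame(exemplar = base$exemplar, duration_s = base$duration_s,
               iti_s = iti, stringsAsFactors = FALSE)
  )
  rownames(trials) <- NULL
  new_schedule(trials, "training", as.integer(seed))
}

#' Training-phase pass criterion
#'
#' Entry to the experimental phase requires a strict majority above 80%
#' correct: 13 of 16 trials under the standard design.
#'
#' @param n_correct Integer count of correct training responses.
#' @param n_trials Total training trials (default 16).
#' @return `TRUE` iff `n_correct / n_trials > 0.80`.
#' @export
passes_training <- function(n_correct, n_trials = 16L) {
  if (any(n_correct < 0) || any(n_correct > n_trials)) {
    stop("n_correct must lie in [0, n_trials]", call. = FALSE)
  }
  n_correct / n_trials > 0.80
}

# Order 28 block items (7 per condition) so no two consecutive items share a
# condition. Shuffle-and-check with bounded retries, then a constructive
# greedy fallback (always pick from the most-constrained remaining condition,
# which is feasible whenever max count <= ceiling(n/2)).
order_block_conditions <- function(items, max_retries = 10000L) {
  n <- length(items)
  for (k in seq_len(max_retries)) {
    ord <- sample.int(n)
    if (!any(items[ord][-1L] == items[ord][-n])) return(ord)
  }
  # constructive fallback: indices per condition, consume largest-first
  pool <- split(seq_len(n), items)
  pool <- lapply(pool, sample) # seeded shuffle within condition
  out <- integer(n)
  prev <- ""
  for (i in seq_len(n)) {
    counts <- vapply(pool, length, 0L)
    eligible <- names(counts)[counts > 0L & names(counts) != prev]
    if (length(eligible) == 0L) {
      stop(sprintf("scheduling error: adjacency constraint unsatisfiable (seed state exhausted at position %d)", i),
           call. = FALSE)
    }
    pick <- eligible[which.max(counts[eligible])]
    out[i] <- pool[[pick]][1L]
    pool[[pick]] <- pool[[pick]][-1L]
    prev <- pick
  }
  out
}

#' Build the experimental-phase schedule
#'
#' Each block presents all 28 duration-by-condition combinations (7 durations
#' x 4 conditions) exactly once, pseudo-randomized so that no two consecutive
#' trials within a block share a condition, with inter-trial intervals drawn
#' uniformly between 1 and 3 s. Eight blocks give the standard 224 trials.
#'
#' @param exemplars Named character vector of 8 sound identifiers.
#' @param n_blocks Number of blocks (default 8).
#' @param seed Integer seed; the schedule is a deterministic function of it.
#' @param across_blocks If `TRUE`, additionally forbid a condition repeat
#'   across the block boundary (default `FALSE`: participants may pause
#'   between blocks).
#' @param max_retries Bounded shuffle-and-check retries per block before the
#'   constructive fallback.
#' @return A `bisect_schedule` data.frame (see [build_training_schedule()]).
#' @export
build_experiment_schedule <- function(exemplars = default_exemplars(),
                                      n_blocks = 8L, seed = 1L,
                                      across_blocks = FALSE,
                                      max_retries = 10000L) {
  check_exemplars(exemplars)
  if (n_blocks < 1L) stop("n_blocks must be >= 1", call. = FALSE)
  conds <- condition_grid()$condition
  durs <- bisection_durations()
  cells <- expand.grid(duration_s = durs, condition = conds,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  trials <- with_temp_seed(seed, {
    prev_last <- ""
    blocks <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      repeat {
        ord <- order_block_conditions(cells$condition, max_retries)
        blk <- cells[ord, , drop = FALSE]
        # under across_blocks, re-draw if the boundary pair repeats a condition
        if (!across_blocks || b == 1L || blk$condition[1L] != prev_last) break
      }
      prev_last <- blk$condition[nrow(blk)]
      blk$block <- b
      blocks[[b]] <- blk
    }
    do.call(rbind, blocks)
  })
  # round-robin exemplar assignment within each block x condition, starting
  # offset seeded so the two exemplars alternate across duration cells
  ex_by_cond <- split(unname(exemplars), names(exemplars))
  offsets <- with_temp_seed(seed + 1L,
                            stats::setNames(sample(0:1, length(conds), replace = TRUE), conds))
  trials$exemplar <- NA_character_
  for (b in unique(trials$block)) {
    for (cond in conds) {
      idx <- which(trials$block == b & trials$condition == cond)
      k <- (seq_along(idx) - 1L + offsets[[cond]] + b - 1L) %% 2L + 1L
      trials$exemplar[idx] <- ex_by_cond[[cond]][k]
    }
  }
  trials$iti_s <- with_temp_seed(seed + 2L, stats::runif(nrow(trials), 1, 3))
  out <- cbind(
    data.frame(phase = "experimental", block = trials$block,
               trial = seq_len(nrow(trials))),
    split_condition(trials$condition),
    data.frame(exemplar = trials$exemplar, duration_s = trials$duration_s,
               iti_s = trials$iti_s, stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  new_schedule(out, "experimental", as.integer(seed))
}

#' Validate a schedule against the design invariants
#'
#' Checks phase-appropriate durations, per-block completeness of the 28
#' duration-by-condition cells, the within-block adjacency constraint, and
#' ITI bounds. Returns human-readable violation descriptions naming trial
#' indices; an empty character vector means the schedule is valid.
#'
#' @param s A schedule data.frame as produced by the builders.
#' @return Character vector of violations (length 0 if valid).
#' @export
validate_schedule <- function(s) {
  violations <- character(0)
  need <- c("phase", "block", "trial", "condition_category",
            "condition_valence", "exemplar", "duration_s", "iti_s")
  missing_cols <- setdiff(need, names(s))
  if (length(missing_cols)) {
    return(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")))
  }
  cond <- paste(s$condition_category, s$condition_valence, sep = "-")
  phase <- unique(s$phase)
  if (any(s$iti_s < 1 - 1e-9 | s$iti_s > 3 + 1e-9, na.rm = TRUE)) {
    bad <- which(s$iti_s < 1 - 1e-9 | s$iti_s > 3 + 1e-9)
    violations <- c(violations,
                    sprintf("iti outside [1, 3] s at trials %s",
                            paste(utils::head(bad, 10L), collapse = ", ")))
  }
  if ("training" %in% phase) {
    tr <- s[s$phase == "training", , drop = FALSE]
    if (nrow(tr) != 16L) {
      violations <- c(violations,
                      sprintf("training phase has %d trials, expected 16", nrow(tr)))
    }
    bad <- tr$trial[!tr$duration_s %in% reference_durations()]
    if (length(bad)) {
      violations <- c(violations,
                      sprintf("training durations must be 2 or 5 s; trials %s",
                              paste(bad, collapse = ", ")))
    }
    pair <- table(paste(tr$exemplar, tr$duration_s))
    if (any(pair != 1L) || length(pair) != 16L) {
      violations <- c(violations,
                      "training must present each (exemplar, reference) pair exactly once")
    }
  }
  if ("experimental" %in% phase) {
    ex <- s[s$phase == "experimental", , drop = FALSE]
    cond_ex <- cond[s$phase == "experimental"]
    durs <- bisection_durations()
    if (!all(ex$duration_s %in% durs)) {
      bad <- ex$trial[!ex$duration_s %in% durs]
      violations <- c(violations,
                      sprintf("experimental durations outside the 7-value set at trials %s",
                              paste(utils::head(bad, 10L), collapse = ", ")))
    }
    for (b in sort(unique(ex$block))) {
      in_b <- ex$block == b
      blk <- ex[in_b, , drop = FALSE]
      cell <- table(paste(cond_ex[in_b], blk$duration_s))
      if (length(cell) != 28L || any(cell != 1L)) {
        short <- names(cell)[cell != 1L]
        violations <- c(violations,
                        sprintf("block %d does not contain the 28 duration-condition cells exactly once%s",
                                b, if (length(short)) paste0(" (", paste(utils::head(short, 5L), collapse = "; "), ")") else ""))
      }
      cb <- cond_ex[in_b]
      adj <- which(cb[-1L] == cb[-length(cb)])
      if (length(adj)) {
        violations <- c(violations,
                        sprintf("block %d repeats a condition at consecutive trials %s",
                                b, paste(blk$trial[adj], collapse = ", ")))
      }
    }
  }
  violations
}

#' Write or read a schedule CSV
#'
#' Columns: phase, block, trial, condition_category, condition_valence,
#' exemplar, duration_s (one decimal), iti_s. UTF-8, "." decimal separator.
#'
#' @param s Schedule data.frame.
#' @param path File path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns the schedule data.frame.
#' @export
write_schedule <- function(s, path) {
  out <- as.data.frame(s)
  out$duration_s <- sprintf("%.1f", out$duration_s)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("phase", "block", "trial", "condition_category",
            "condition_valence", "exemplar", "duration_s", "iti_s")
  missing_cols <- setdiff(need, names(s))
  if (length(missing_cols)) {
    stop(sprintf("schedule schema mismatch; missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  s
}
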