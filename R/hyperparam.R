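# Pairwise (strength-2) combinatorial design over hyper-parameter levels:
# a greedy covering-array generator plus an exhaustive coverage checker,
# and the fixed 10-run screening table used for the published experiments.

#' Hyper-parameter factor space
#'
#' An ordered set of factors, each with a finite ordered level set.  The
#' default space is the screening space used for the classifier: learning
#' rate {0.05, 0.1, 0.15}, dropout {0.3, 0.5, 0.8}, momentum
#' {0.5, 0.7, 0.9}.
#'
#' @param ... named level vectors, e.g.
#'   `factor_space(lr = c(0.05, 0.1), dropout = c(0.3, 0.5))`.
#' @return a `factor_space`: named list of level vectors.
#' @export
factor_space <- function(...) {
  factors <- list(...)
  if (!length(factors)) {
    factors <- list(learning_rate = c(0.05, 0.1, 0.15),
                    dropout = c(0.3, 0.5, 0.8),
                    momentum = c(0.5, 0.7, 0.9))
  }
  if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
    stop("every factor must be named")
  }
  for (nm in names(factors)) {
    lv <- factors[[nm]]
    if (!length(lv)) stop("factor ", nm, " has an empty level set")
    if (anyDuplicated(lv)) stop("factor ", nm, " has duplicate levels")
  }
  structure(factors, class = "factor_space")
}

# All cross-factor level pairs as a data frame of
# (factor i, level index a, factor j, level index b), i < j.
all_pairs <- function(space) {
  nf <- length(space)
  out <- list()
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      g <- expand.grid(a = seq_along(space[[i]]), b = seq_along(space[[j]]))
      out[[length(out) + 1L]] <- data.frame(i = i, a = g$a, j = j, b = g$b)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(i = integer(), a = integer(), j = integer(), b = integer())
}

pair_key <- function(i, a, j, b) paste(i, a, j, b, sep = ":")

row_pair_keys <- function(row_idx) {
  nf <- length(row_idx)
  keys <- character(0)
  for (i in seq_len(max(nf - 1L, 0L))) {
    for (j in seq_len(nf)[-seq_len(i)]) {
      keys <- c(keys, pair_key(i, row_idx[i], j, row_idx[j]))
    }
  }
  keys
}

#' Generate a strength-2 covering array
#'
#' Greedy one-row-at-a-time construction: each row starts from an uncovered
#' cross-factor level pair and fills the remaining factors to maximize
#' newly covered pairs; several candidate rows are tried per step and the
#' best kept.  Ties break by factor order then level order, so output is
#' deterministic for a given seed.
#'
#' @param space a [factor_space()].
#' @param strength only 2 is supported.
#' @param seed RNG seed for candidate exploration.
#' @param n_candidates candidate rows tried per step.
#' @return a `covering_array`: list with `rows` (data frame, one column
#'   per factor), `covered_pairs`, `total_pairs`, `is_complete`.
#' @export
generate_covering_array <- function(space, strength = 2, seed = 1L,
                                    n_candidates = 30L) {
  stopifnot(inherits(space, "factor_space"))
  if (strength != 2) stop("only strength-2 (pairwise) designs are supported")
  nf <- length(space)
  sizes <- lengths(space)
  if (nf < 2L) {
    rows <- data.frame(seq_along(space[[1L]]))
    names(rows) <- names(space)
    rows[[1L]] <- space[[1L]]
    return(new_covering_array(rows, space))
  }
  pairs <- all_pairs(space)
  uncovered <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(pairs))) {
    assign(pair_key(pairs$i[r], pairs$a[r], pairs$j[r], pairs$b[r]),
           TRUE, envir = uncovered)
  }
  n_uncov <- nrow(pairs)
  rows_idx <- list()
  with_seed(seed, while (n_uncov > 0L) {
    seeds_left <- ls(uncovered)
    n_try <- min(n_candidates, length(seeds_left))
    starts <- seeds_left[seq_len(n_try)]
    best_row <- NULL; best_gain <- -1L
    for (st in starts) {
      parts <- as.integer(strsplit(st, ":", fixed = TRUE)[[1L]])
      row <- rep(NA_integer_, nf)
      row[parts[1L]] <- parts[2L]; row[parts[3L]] <- parts[4L]
      free <- which(is.na(row))
      if (length(free) > 1L) free <- sample(free)
      for (f in free) {
        gains <- vapply(seq_len(sizes[f]), function(lv) {
          trial <- row; trial[f] <- lv
          fixed <- which(!is.na(trial))
          sum(vapply(setdiff(fixed, f), function(g) {
            i <- min(f, g); j <- max(f, g)
            exists(pair_key(i, trial[i], j, trial[j]), envir = uncovered)
          }, logical(1)))
        }, 0L)
        row[f] <- which.max(gains)
      }
      gain <- sum(vapply(row_pair_keys(row), exists, logical(1),
                         envir = uncovered))
      if (gain > best_gain) { best_gain <- gain; best_row <- row }
    }
    for (k in row_pair_keys(best_row)) {
      if (exists(k, envir = uncovered)) {
        rm(list = k, envir = uncovered)
        n_uncov <- n_uncov - 1L
      }
    }
    rows_idx[[length(rows_idx) + 1L]] <- best_row
  })
  m <- do.call(rbind, rows_idx)
  rows <- as.data.frame(lapply(seq_len(nf), function(f) space[[f]][m[, f]]))
  names(rows) <- names(space)
  new_covering_array(rows, space)
}

new_covering_array <- function(rows, space) {
  cov <- verify_coverage_impl(rows, space)
  structure(list(rows = rows, covered_pairs = cov$covered,
                 total_pairs = cov$total,
                 is_complete = cov$covered == cov$total),
            class = "covering_array")
}

#' Verify pairwise coverage of a design
#'
#' Exhaustively enumerates every cross-factor level pair and checks that it
#' appears in at least one row.
#'
#' @param rows a `covering_array`, or a data frame with one column per
#'   factor of `space` (levels as values).
#' @param space a [factor_space()].
#' @param strength only 2 is supported.
#' @return list with `covered` (count), `total`, `missing` (data frame of
#'   uncovered pairs: factor names and levels), `is_complete`.
#' @export
verify_coverage <- function(rows, space, strength = 2) {
  if (strength != 2) stop("only strength-2 (pairwise) designs are supported")
  if (inherits(rows, "covering_array")) rows <- rows$rows
  cov <- verify_coverage_impl(rows, space)
  cov$is_complete <- cov$covered == cov$total
  cov
}

verify_coverage_impl <- function(rows, space) {
  pairs <- all_pairs(space)
  if (!nrow(pairs)) {
    return(list(covered = 0L, total = 0L,
                missing = data.frame()))
  }
  fac_names <- names(space)
  hit <- logical(nrow(pairs))
  if (nrow(rows)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; j <- pairs$j[r]
      la <- space[[i]][pairs$a[r]]; lb <- space[[j]][pairs$b[r]]
      hit[r] <- any(rows[[fac_names[i]]] == la & rows[[fac_names[j]]] == lb)
    }
  }
  missing <- pairs[!hit, , drop = FALSE]
  missing_df <- data.frame(
    factor_1 = fac_names[missing$i],
    level_1 = vapply(seq_len(nrow(missing)), function(r)
      space[[missing$i[r]]][missing$a[r]], numeric(1)),
    factor_2 = fac_names[missing$j],
    level_2 = vapply(seq_len(nrow(missing)), function(r)
      space[[missing$j[r]]][missing$b[r]], numeric(1)),
    stringsAsFactors = FALSE)
  list(covered = sum(hit), total = nrow(pairs), missing = missing_df)
}

#' @export
print.covering_array <- function(x, ...) {
  cat(sprintf("<covering_array> %d rows, %d/%d pairs covered%s\n",
              nrow(x$rows), x$covered_pairs, x$total_pairs,
              if (x$is_complete) " (complete)" else ""))
  print(x$rows)
  invisible(x)
}

#' The published 10-run hyper-parameter screening table
#'
#' The fixed pairwise design over learning rate, dropout and momentum used
#' for the reference experiments (10 runs covering all 27 cross-factor
#' level pairs).  Shipped as a constant so experiments can reproduce the
#' exact combinations rather than regenerate an equivalent design.
#'
#' @return data frame with columns `run`, `learning_rate`, `dropout`,
#'   `momentum`.
#' @export
reference_hparam_table <- function() {
  data.frame(
    run = 1:10,
    learning_rate = c(0.10, 0.15, 0.05, 0.15, 0.05,
                      0.10, 0.15, 0.05, 0.10, 0.15),
    dropout = c(0.8, 0.3, 0.5, 0.8, 0.3, 0.5, 0.3, 0.8, 0.3, 0.5),
    momentum = c(0.5, 0.9, 0.5, 0.7, 0.7, 0.9, 0.5, 0.9, 0.7, 0.7))
}
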