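#' Enumerate the model-order grid
#'
#' All (numerator order, denominator order) combinations with no
#' feedthrough: `0 <= num_order <= den_order - 1` for denominator orders
#' `1 .. max_den`, sorted by denominator then numerator order. The grid
#' is triangular: `max_den * (max_den + 1) / 2` combinations — 15 at
#' `max_den = 5`, 55 at `max_den = 10`.
#'
#' @param max_den largest denominator order (>= 1).
#' @return Data frame with columns `num_order`, `den_order`.
#' @export
enumerate_order_grid <- function(max_den = 5) {
  if (max_den < 1) stop("max_den must be at least 1", call. = FALSE)
  grid <- do.call(rbind, lapply(seq_len(max_den), function(m)
    data.frame(num_order = 0:(m - 1L), den_order = m)))
  rownames(grid) <- NULL
  grid
}

#' Fit the order grid over subjects and period pairs
#'
#' For every subject, period pair and order combination: align the
#' pair's SAECGs on their R peaks, estimate the transfer function and
#' record its goodness of fit. A cell whose estimation fails (or whose
#' simulation is non-finite) is recorded as failed with a warning and
#' excluded from the aggregated means.
#'
#' @param subjects list of [subject_saecgs()] (each with all three
#'   periods).
#' @param pairs character vector of pair labels to fit.
#' @param max_den largest denominator order of the grid.
#' @param ... passed to [estimate_tf()].
#' @return An `"order_grid"`: `cells` (long data frame: `subject_id`,
#'   `pair`, `num_order`, `den_order`, `gf`, `converged`) plus the `grid`
#'   enumerated.
#' @export
fit_grid <- function(subjects, pairs = pair_labels(), max_den = 5, ...) {
  if (length(subjects) < 1L) stop("need at least one subject", call. = FALSE)
  grid <- enumerate_order_grid(max_den)
  rows <- vector("list", length(subjects) * length(pairs) * nrow(grid))
  k <- 0L
  for (sub in subjects) {
    for (pr in pairs) {
      pp <- period_pair(pr)
      aligned <- pair_saecgs(sub[[pp$input_period]], sub[[pp$output_period]])
      for (g in seq_len(nrow(grid))) {
        gf <- NA_real_; conv <- FALSE
        fit <- tryCatch(
          estimate_tf(aligned$x, aligned$y, grid$num_order[g],
                      grid$den_order[g], ...),
          error = function(e) NULL)
        if (!is.null(fit) && is.finite(fit$gf)) {
          gf <- fit$gf; conv <- fit$converged
        } else {
          warning(sprintf(
            "grid cell failed (subject %s, %s, orders %d/%d); excluded",
            sub$subject_id, pr, grid$num_order[g], grid$den_order[g]),
            call. = FALSE)
        }
        k <- k + 1L
        rows[[k]] <- data.frame(subject_id = as.character(sub$subject_id),
                                pair = pr, num_order = grid$num_order[g],
                                den_order = grid$den_order[g], gf = gf,
                                converged = conv, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(cells = do.call(rbind, rows), grid = grid),
            class = "order_grid")
}

#' Aggregate an order grid into a per-order mean-GF table
#'
#' One row per order combination with the mean goodness of fit per period
#' pair (across subjects, failed cells excluded) and `mean_gf`, the
#' unweighted mean of the pair means.
#'
#' @param grid an `"order_grid"` from [fit_grid()], or its long `cells`
#'   data frame.
#' @return Data frame: `num_order`, `den_order`, one `gf_<pair>` column
#'   per pair, `mean_gf`.
#' @export
order_grid_table <- function(grid) {
  cells <- if (inherits(grid, "order_grid")) grid$cells else grid
  pairs <- unique(cells$pair)
  combos <- unique(cells[c("num_order", "den_order")])
  combos <- combos[order(combos$den_order, combos$num_order), ]
  rownames(combos) <- NULL
  for (pr in pairs) {
    combos[[paste0("gf_", pr)]] <- vapply(seq_len(nrow(combos)), function(i) {
      sel <- cells$pair == pr &
        cells$num_order == combos$num_order[i] &
        cells$den_order == combos$den_order[i] & !is.na(cells$gf)
      if (!any(sel)) NA_real_ else mean(cells$gf[sel])
    }, numeric(1))
  }
  pair_cols <- paste0("gf_", pairs)
  combos$mean_gf <- rowMeans(combos[pair_cols])
  combos
}

## Overall mean-GF column of a grid table, tolerant of either a ready
## mean_gf column or pair columns to average.
.table_mean_gf <- function(table, cols = NULL) {
  if (!is.null(cols)) return(rowMeans(table[cols]))
  if ("mean_gf" %in% names(table)) return(table$mean_gf)
  pair_cols <- grep("^gf_", names(table), value = TRUE)
  if (length(pair_cols) == 0L)
    stop("table has neither a mean_gf column nor gf_<pair> columns",
         call. = FALSE)
  rowMeans(table[pair_cols])
}

#' Select the optimized model order from a grid table
#'
#' Returns the order combination with the highest mean goodness of fit.
#' Mean GFs are compared at report precision (`digits` decimals, matching
#' the two-decimal grid report), and ties — including fits whose
#' difference falls below that resolution — are broken by parsimony:
#' smaller denominator order first, then smaller numerator order.
#'
#' @param table a grid table ([order_grid_table()] layout, or any data
#'   frame with `num_order`, `den_order` and either `mean_gf` or
#'   `gf_<pair>` columns).
#' @param digits precision (decimal places) at which mean GFs are
#'   compared; `Inf` compares exactly.
#' @return A list: `num_order`, `den_order`, `mean_gf` (unrounded).
#' @export
select_optimized_order <- function(table, digits = 2) {
  mg <- .table_mean_gf(table)
  ok <- is.finite(mg)
  if (!any(ok)) stop("all grid rows failed", call. = FALSE)
  cmp <- if (is.finite(digits)) round(mg, digits) else mg
  cand <- which(ok & cmp == max(cmp[ok]))
  best <- cand[order(table$den_order[cand], table$num_order[cand])][1L]
  list(num_order = table$num_order[best], den_order = table$den_order[best],
       mean_gf = mg[best])
}

#' @rdname select_optimized_order
#' @param pair pair label: the selection is restricted to that pair's
#'   mean-GF column.
#' @export
select_pair_order <- function(table, pair, digits = 2) {
  col <- paste0("gf_", pair)
  if (!col %in% names(table))
    stop(sprintf("table has no column '%s'", col), call. = FALSE)
  mg <- table[[col]]
  ok <- is.finite(mg)
  if (!any(ok)) stop("all grid rows failed", call. = FALSE)
  cmp <- if (is.finite(digits)) round(mg, digits) else mg
  cand <- which(ok & cmp == max(cmp[ok]))
  best <- cand[order(table$den_order[cand], table$num_order[cand])][1L]
  list(num_order = table$num_order[best], den_order = table$den_order[best],
       mean_gf = mg[best])
}
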