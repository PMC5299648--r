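#' Period pairs of the trial design
#'
#' The three input/output pairings analysed: `bda` (before -> during),
#' `daa` (during -> after) and `baa` (before -> after); in each pair the
#' earlier period's SAECG is the input signal and the later period's the
#' output.
#'
#' @param label one of `"bda"`, `"daa"`, `"baa"`.
#' @return A `"period_pair"` list: `label`, `input_period`,
#'   `output_period`.
#' @export
period_pair <- function(label = c("bda", "daa", "baa")) {
  label <- match.arg(label)
  io <- switch(label,
               bda = c("before", "during"),
               daa = c("during", "after"),
               baa = c("before", "after"))
  structure(list(label = label, input_period = io[1], output_period = io[2]),
            class = "period_pair")
}

#' @rdname period_pair
#' @export
pair_labels <- function() c("bda", "daa", "baa")

#' One subject's three period SAECGs
#'
#' @param subject_id identifier.
#' @param before,during,after [saecg()] objects sharing one sampling
#'   frequency.
#' @return A `"subject_saecgs"` list.
#' @export
subject_saecgs <- function(subject_id, before, during, after) {
  for (s in list(before, during, after))
    if (!inherits(s, "saecg")) stop("all periods must be saecg objects",
                                    call. = FALSE)
  if (length(unique(c(before$fs, during$fs, after$fs))) != 1L)
    stop("all period SAECGs must share one sampling frequency",
         call. = FALSE)
  structure(list(subject_id = subject_id, before = before, during = during,
                 after = after),
            class = "subject_saecgs")
}

#' Align two SAECGs on their R peaks
#'
#' Shifts the two averaged beats so their R peaks coincide and truncates
#' both to the common overlap: `min` of the samples available before R and
#' `min` of the samples available from R onward. The returned vectors have
#' equal length with the R peak at the same position.
#'
#' @param input_saecg,output_saecg [saecg()] objects with the same `fs`.
#' @return List with `x` (aligned input), `y` (aligned output),
#'   `r_offset` (shared samples-before-R), `fs`.
#' @export
pair_saecgs <- function(input_saecg, output_saecg) {
  stopifnot(inherits(input_saecg, "saecg"), inherits(output_saecg, "saecg"))
  if (input_saecg$fs != output_saecg$fs)
    stop("SAECGs must share a sampling frequency", call. = FALSE)
  r1 <- input_saecg$r_offset; r2 <- output_saecg$r_offset
  n1 <- length(input_saecg$samples); n2 <- length(output_saecg$samples)
  pre <- min(r1, r2)                    # samples strictly before R
  post <- min(n1 - r1, n2 - r2)         # samples from R (inclusive) to end
  if (pre + post < 10L)
    stop("aligned overlap shorter than 10 samples", call. = FALSE)
  x <- input_saecg$samples[(r1 - pre + 1L):(r1 + post)]
  y <- output_saecg$samples[(r2 - pre + 1L):(r2 + post)]
  list(x = x, y = y, r_offset = pre, fs = input_saecg$fs)
}

#' Fit one subject's individual transfer function for a period pair
#'
#' Aligns the pair's input- and output-period SAECGs on their R peaks,
#' then estimates the transfer function at the given orders by
#' [estimate_tf()]. The result is tagged with the subject and pair.
#'
#' @param subject a [subject_saecgs()].
#' @param pair a [period_pair()] or its label.
#' @param num_order,den_order model orders.
#' @param ... passed to [estimate_tf()].
#' @return A `"tf_fit"` with added fields `subject_id` and `pair`.
#' @export
fit_itf <- function(subject, pair, num_order, den_order, ...) {
  stopifnot(inherits(subject, "subject_saecgs"))
  if (!inherits(pair, "period_pair")) pair <- period_pair(pair)
  aligned <- pair_saecgs(subject[[pair$input_period]],
                         subject[[pair$output_period]])
  fit <- estimate_tf(aligned$x, aligned$y, num_order, den_order, ...)
  fit$subject_id <- subject$subject_id
  fit$pair <- pair$label
  fit
}

#' Average individual transfer functions into a generalized one
#'
#' The generalized transfer function (GTF) is the per-order arithmetic
#' mean of the individual transfer functions' coefficients: each
#' numerator coefficient is averaged across subjects, and likewise each
#' denominator coefficient. Because every individual denominator is
#' monic, the average denominator is monic by construction. All
#' contributing models must share the same orders.
#'
#' @param itfs list of [dtf()] or `"tf_fit"` objects.
#' @param pair optional pair label carried on the result.
#' @return A `"gtf"` object: `tf`, `pair`, `n_subjects`, `source_ids`.
#' @export
average_itfs <- function(itfs, pair = NULL) {
  if (length(itfs) < 1L) stop("need at least one ITF", call. = FALSE)
  tfs <- lapply(itfs, function(f) if (inherits(f, "tf_fit")) f$tf else f)
  if (!all(vapply(tfs, is_dtf, logical(1))))
    stop("itfs must be dtf or tf_fit objects", call. = FALSE)
  nn <- vapply(tfs, function(t) length(t$num), integer(1))
  nd <- vapply(tfs, function(t) length(t$den), integer(1))
  if (length(unique(nn)) != 1L || length(unique(nd)) != 1L)
    stop("all ITFs must share the same model orders", call. = FALSE)
  num <- colMeans(do.call(rbind, lapply(tfs, `[[`, "num")))
  den <- colMeans(do.call(rbind, lapply(tfs, `[[`, "den")))
  den[1L] <- 1                          # mean of exact ones stays exact
  ids <- vapply(seq_along(itfs), function(i) {
    f <- itfs[[i]]
    if (inherits(f, "tf_fit") && !is.null(f$subject_id))
      as.character(f$subject_id) else as.character(i)
  }, character(1))
  structure(list(tf = dtf(num, den), pair = pair,
                 n_subjects = length(itfs), source_ids = ids),
            class = "gtf")
}

#' @export
print.gtf <- function(x, ...) {
  cat(sprintf("Generalized transfer function (%s, averaged over %d subjects)\n",
              if (is.null(x$pair)) "unlabelled pair" else toupper(x$pair),
              x$n_subjects))
  print(x$tf)
  invisible(x)
}

#' Evaluate individual versus generalized models for one period pair
#'
#' For each subject the pair's aligned input SAECG is simulated through
#' (a) that subject's individual transfer function and (b) the
#' generalized transfer function, and each simulation is scored by
#' [goodness_of_fit()] against the subject's measured output SAECG.
#' Either model may win for a given subject; the table permits both
#' signs of the difference.
#'
#' @param subjects list of [subject_saecgs()].
#' @param itfs list of the same subjects' ITFs (`"tf_fit"` or [dtf()]),
#'   in the same order.
#' @param gtf a `"gtf"` (orders must match the ITFs).
#' @param pair a [period_pair()] or label.
#' @return A `"model_eval"` list: `table` (per-subject `subject_id`,
#'   `gf_itf`, `gf_gtf`), `mean_itf`, `mean_gtf`, `sd_itf`, `sd_gtf`
#'   (sample SDs, n-1), and `mean_diff` (= `mean_itf - mean_gtf`).
#' @export
evaluate_models <- function(subjects, itfs, gtf, pair) {
  if (!inherits(pair, "period_pair")) pair <- period_pair(pair)
  stopifnot(inherits(gtf, "gtf"), length(subjects) == length(itfs))
  gf_itf <- numeric(length(subjects))
  gf_gtf <- numeric(length(subjects))
  ids <- vapply(subjects, function(s) as.character(s$subject_id),
                character(1))
  for (i in seq_along(subjects)) {
    aligned <- pair_saecgs(subjects[[i]][[pair$input_period]],
                           subjects[[i]][[pair$output_period]])
    itf <- if (inherits(itfs[[i]], "tf_fit")) itfs[[i]]$tf else itfs[[i]]
    if (num_order(itf) != num_order(gtf$tf) ||
        den_order(itf) != den_order(gtf$tf))
      stop("GTF orders must match the ITF orders", call. = FALSE)
    gf_itf[i] <- goodness_of_fit(aligned$y, simulate_tf(itf, aligned$x))
    gf_gtf[i] <- goodness_of_fit(aligned$y, simulate_tf(gtf$tf, aligned$x))
  }
  tab <- data.frame(subject_id = ids, gf_itf = gf_itf, gf_gtf = gf_gtf,
                    stringsAsFactors = FALSE)
  structure(list(pair = pair$label, table = tab,
                 mean_itf = mean(gf_itf), mean_gtf = mean(gf_gtf),
                 sd_itf = stats::sd(gf_itf), sd_gtf = stats::sd(gf_gtf),
                 mean_diff = mean(gf_itf) - mean(gf_gtf)),
            class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf("%s: mean GF ITF %.2f (SD %.2f), GTF %.2f (SD %.2f), diff %.2f\n",
              toupper(x$pair), x$mean_itf, x$sd_itf, x$mean_gtf, x$sd_gtf,
              x$mean_diff))
  invisible(x)
}

#' Table-2-style aggregation of per-subject fit columns
#'
#' Given a per-subject table of goodness-of-fit columns, appends the
#' column means and sample standard deviations (n-1), reproducing the
#' Avg/SD layout of the subject report. Used both by the pipeline report
#' writer and, as a worked example, on the published reference values.
#'
#' @param tab data frame whose first column identifies subjects and whose
#'   remaining columns are numeric GF values.
#' @return A list: `avg` and `sd` (named numeric vectors over the GF
#'   columns) and `table` (the input with `Avg` and `SD` rows appended).
#' @export
summarize_subject_table <- function(tab) {
  num_cols <- names(tab)[-1L]
  avg <- vapply(tab[num_cols], mean, numeric(1))
  sdv <- vapply(tab[num_cols], stats::sd, numeric(1))
  out <- tab
  out[] <- lapply(out, as.character)
  out[nrow(out) + 1L, ] <- c("Avg", formatC(avg, format = "f", digits = 2))
  out[nrow(out) + 1L, ] <- c("SD", formatC(sdv, format = "f", digits = 2))
  list(avg = avg, sd = sdv, table = out)
}
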