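# Data model for clustered multi-treatment survival data: validation,
# CSV/TSV input and output, and the Kaplan-Meier baseline utility.

#' Construct a clustered survival data set
#'
#' Validates and assembles one row per subject: an observed follow-up time
#' (months), an event indicator, a treatment label (J >= 2 arms), a cluster
#' identifier (K >= 2 clusters, e.g. treating institutions), and a matrix of
#' pre-treatment covariates. Character or factor covariate columns are
#' one-hot expanded with the reference level dropped; cluster labels are
#' re-indexed 1..K in sorted order of the original labels. Missing values
#' are an error, never imputed.
#'
#' @param y observed times, all positive (months).
#' @param delta event indicators: 1 = failure observed, 0 = right-censored.
#' @param a treatment labels (factor, character or numeric).
#' @param cluster cluster identifiers.
#' @param x covariate matrix or data frame (may be `NULL` for none).
#' @return an object of class `clustered_survival_data` with elements
#'   `y`, `delta`, `a` (factor), `cluster` (integer codes 1..K),
#'   `cluster_labels`, `x` (numeric matrix), and counts `n`, `K`, `J`.
#' @export
clustered_survival_data <- function(y, delta, a, cluster, x = NULL) {
  n <- length(y)
  if (n == 0) stop("empty data")
  if (length(delta) != n || length(a) != n || length(cluster) != n)
    stop("y, delta, a and cluster must have equal length")
  bad <- which(is.na(y) | is.na(delta) | is.na(a) | is.na(cluster))
  if (!is.null(x)) {
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    if (nrow(x) != n) stop("x must have one row per subject")
    bad <- sort(unique(c(bad, which(!stats::complete.cases(x)))))
  }
  if (length(bad))
    stop("missing values in rows: ", paste(utils::head(bad, 10), collapse = ", "))
  bady <- which(!(y > 0))
  if (length(bady))
    stop("y must be positive; offending rows: ",
         paste(utils::head(bady, 10), collapse = ", "))
  badd <- which(!(delta %in% c(0, 1)))
  if (length(badd))
    stop("delta must be 0 or 1; offending rows: ",
         paste(utils::head(badd, 10), collapse = ", "))

  a <- factor(a)
  if (nlevels(a) < 2) stop("need at least 2 treatment arms")
  clab <- if (is.numeric(cluster)) as.character(sort(unique(cluster)))
          else sort(unique(as.character(cluster)))
  if (length(clab) < 2) stop("need at least 2 clusters")
  cl <- match(as.character(cluster), clab)

  xm <- NULL
  if (!is.null(x) && ncol(x) > 0) {
    cols <- lapply(seq_along(x), function(j) {
      v <- x[[j]]
      nm <- names(x)[j]
      if (is.numeric(v) || is.logical(v)) {
        m <- matrix(as.numeric(v), ncol = 1)
        colnames(m) <- nm
        m
      } else {
        f <- factor(v)
        m <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(m) <- paste0(nm, levels(f)[-1])
        m
      }
    })
    xm <- do.call(cbind, cols)
    rownames(xm) <- NULL
  }

  structure(
    list(y = as.numeric(y), delta = as.integer(delta), a = a,
         cluster = cl, cluster_labels = clab, x = xm,
         n = n, K = length(clab), J = nlevels(a)),
    class = "clustered_survival_data")
}

#' @export
print.clustered_survival_data <- function(x, ...) {
  cat("Clustered survival data: ", x$n, " subjects, ", x$K, " clusters, ",
      x$J, " treatment arms (", paste(levels(x$a), collapse = ", "), ")\n",
      sep = "")
  cat(sprintf("  events: %d (%.1f%% censored), covariates: %d\n",
              sum(x$delta), 100 * mean(x$delta == 0),
              if (is.null(x$x)) 0L else ncol(x$x)))
  invisible(x)
}

#' Read clustered survival data from a delimited file
#'
#' @param path CSV (or TSV) file with a header row.
#' @param time,event,treatment,cluster column names in the file.
#' @param covariates character vector of covariate column names; `NULL`
#'   uses every remaining column.
#' @param sep field separator; guessed from the file extension by default.
#' @return a validated [clustered_survival_data] object.
#' @export
read_clustered_survival <- function(path, time = "time", event = "event",
                                    treatment = "treatment",
                                    cluster = "cluster",
                                    covariates = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  need <- c(time, event, treatment, cluster, covariates)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("columns not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (is.null(covariates))
    covariates <- setdiff(names(df), c(time, event, treatment, cluster))
  clustered_survival_data(
    y = df[[time]], delta = df[[event]], a = df[[treatment]],
    cluster = df[[cluster]],
    x = if (length(covariates)) df[covariates] else NULL)
}

#' Write clustered survival data to CSV
#'
#' Writes the validated (already expanded) representation, so that
#' [read_clustered_survival] round-trips it.
#'
#' @param data a [clustered_survival_data] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clustered_survival <- function(data, path) {
  stopifnot(inherits(data, "clustered_survival_data"))
  df <- data.frame(time = data$y, event = data$delta,
                   treatment = as.character(data$a),
                   cluster = data$cluster_labels[data$cluster],
                   stringsAsFactors = FALSE)
  if (!is.null(data$x)) df <- cbind(df, as.data.frame(data$x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator evaluated at every distinct observed time, with
#' tied event times handled by simultaneous multiplication. A thin wrapper
#' around [survival::survfit()] returning a plain step curve.
#'
#' @param y positive observed times.
#' @param delta event indicators (1 = event, 0 = censored).
#' @return an object of class `step_survival_curve`: a list with sorted
#'   `times` and non-increasing `surv` probabilities.
#' @export
kaplan_meier <- function(y, delta) {
  if (length(y) == 0) stop("empty input")
  if (length(delta) != length(y)) stop("y and delta lengths differ")
  if (any(!(y > 0))) stop("y must be positive")
  fit <- survival::survfit(survival::Surv(y, delta) ~ 1)
  times <- sort(unique(y))
  s <- summary(fit, times = times, extend = TRUE)$surv
  structure(list(times = times, surv = s), class = "step_survival_curve")
}

#' @export
print.step_survival_curve <- function(x, ...) {
  cat("Step survival curve on", length(x$times), "time points; S(last) =",
      format(x$surv[length(x$surv)], digits = 4), "\n")
  invisible(x)
}
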