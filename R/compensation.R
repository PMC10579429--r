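# Multichannel preprocessing: spillover-matrix estimation from
# single-fluorophore controls, autofluorescence treated as an extra
# pseudo-fluorophore via regression, and compensation by inverting the
# spillover matrix. Residual autofluorescence noise remains after
# compensation; removing it is what the deconvolution is for.

#' Spillover matrix
#'
#' Rows are fluorophores (optionally plus an autofluorescence
#' pseudo-fluorophore), columns are channels; `S[j, own_channel(j)] = 1`.
#'
#' @param matrix Numeric coefficient matrix with row and column names.
#' @param own_channel Named character vector mapping each fluorophore row
#'   to its own channel.
#' @return An object of class `spillover_matrix`.
#' @export
spillover_matrix <- function(matrix, own_channel) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  if (any(!is.finite(matrix))) stop("spillover coefficients must be finite")
  for (f in rownames(matrix)) {
    oc <- own_channel[[f]]
    if (abs(matrix[f, oc] - 1) > 1e-12)
      stop("diagonal coefficient S[", f, ", ", oc, "] must be 1")
  }
  structure(list(matrix = matrix, own_channel = own_channel),
            class = "spillover_matrix")
}

#' @export
print.spillover_matrix <- function(x, ...) {
  cat("Spillover matrix (rows = fluorophores, columns = channels):\n")
  print(round(x$matrix, 4))
  invisible(x)
}

# robust slope through the origin: IRLS with a redescending bisquare
# weight (MASS::rlm); ordinary least squares behind the flag
slope_through_origin <- function(x, y, robust = TRUE) {
  if (stats::var(x) < 1e-12 * (1 + mean(x)^2))
    stop("control has near-zero variance in its own channel; cannot regress")
  if (!robust) return(sum(x * y) / sum(x * x))
  fit <- suppressWarnings(MASS::rlm(y ~ x - 1, psi = MASS::psi.bisquare,
                                    maxit = 100))
  unname(stats::coef(fit)[1L])
}

#' Estimate the spillover matrix from single-fluorophore controls
#'
#' For each control (cells carrying only fluorophore `j`) and each other
#' channel `k`, the coefficient `S[j, k]` is the slope of a regression of
#' channel `k` on the fluorophore's own channel, through the origin; the
#' own-channel coefficient is fixed to 1. A redescending robust
#' regression suppresses outlier events by default.
#'
#' @param controls Named list of [event_table()]s, one per fluorophore.
#' @param own_channel Named character vector: the channel on which each
#'   fluorophore is read out. Defaults to the control names when those
#'   are channel names.
#' @param robust Use robust regression (default) or ordinary least
#'   squares.
#' @return A [spillover_matrix()].
#' @export
estimate_spillover <- function(controls, own_channel = NULL, robust = TRUE) {
  stopifnot(is.list(controls), length(controls) >= 1L,
            !is.null(names(controls)))
  channels <- controls[[1L]]$channel_names
  if (is.null(own_channel))
    own_channel <- stats::setNames(names(controls), names(controls))
  S <- matrix(0, length(controls), length(channels),
              dimnames = list(names(controls), channels))
  for (f in names(controls)) {
    tab <- controls[[f]]
    oc <- own_channel[[f]]
    if (!oc %in% tab$channel_names)
      stop("control '", f, "' lacks its own channel '", oc, "'")
    xo <- tab$values[, oc]
    for (k in tab$channel_names) {
      S[f, k] <- if (k == oc) 1 else
        slope_through_origin(xo, tab$values[, k], robust = robust)
    }
  }
  spillover_matrix(S, own_channel)
}

#' Treat a channel as an autofluorescence pseudo-fluorophore
#'
#' Designates a channel that carries no real fluorophore as a regressor
#' for the autofluorescence: its spillover row is estimated from the data
#' themselves, and for each channel the residual noise variance after
#' regression is compared with the raw variance. The decomposition only
#' helps where the pseudo-channel correlates with the channel's noise; if
#' it correlates with nothing (`|r| < 0.05` everywhere) a warning is
#' emitted.
#'
#' @param data An [event_table()] of noise-only (unlabeled-cell) events.
#' @param af_channel Channel label to use as the pseudo-fluorophore.
#' @param robust Robust regression flag as in [estimate_spillover()].
#' @return List with `row` (named spillover coefficients for the
#'   pseudo-fluorophore), `variance_raw`, `variance_residual` and
#'   `reduction` per channel.
#' @export
add_autofluorescence_channel <- function(data, af_channel, robust = TRUE) {
  stopifnot(inherits(data, "event_table"))
  if (!af_channel %in% data$channel_names)
    stop("channel '", af_channel, "' not present; available: ",
         paste(data$channel_names, collapse = ", "))
  x <- data$values
  others <- setdiff(data$channel_names, af_channel)
  r <- vapply(others, function(k) stats::cor(x[, af_channel], x[, k]), 1.0)
  if (all(abs(r) < 0.05))
    warning("autofluorescence channel '", af_channel,
            "' is essentially uncorrelated with every other channel; ",
            "the regression will not reduce the noise", call. = FALSE)
  row <- stats::setNames(numeric(ncol(x)), data$channel_names)
  row[af_channel] <- 1
  v_raw <- v_res <- stats::setNames(numeric(length(others)), others)
  for (k in others) {
    s <- slope_through_origin(x[, af_channel], x[, k], robust = robust)
    row[k] <- s
    v_raw[k] <- stats::var(x[, k])
    v_res[k] <- stats::var(x[, k] - s * x[, af_channel])
  }
  list(row = row, variance_raw = v_raw, variance_residual = v_res,
       reduction = v_raw - v_res, correlation = r)
}

#' Apply spillover compensation
#'
#' Multiplies each event row by the inverse of the (square, possibly
#' autofluorescence-augmented) spillover matrix, recovering fluorophore
#' signals up to residual noise. Output channels are relabeled by
#' fluorophore.
#'
#' @param data An [event_table()] whose channels match the spillover
#'   columns.
#' @param S A [spillover_matrix()] (square).
#' @return An [event_table()] of compensated values.
#' @export
apply_compensation <- function(data, S) {
  stopifnot(inherits(data, "event_table"), inherits(S, "spillover_matrix"))
  m <- S$matrix
  if (nrow(m) != ncol(m))
    stop("spillover matrix must be square to be inverted (",
         nrow(m), "x", ncol(m), "); augment or drop channels")
  kappa <- kappa(m, exact = TRUE)
  if (!is.finite(kappa) || kappa > 1e12)
    stop("spillover matrix is numerically singular (condition number ",
         format(kappa, digits = 3), ")")
  x <- data$values[, colnames(m), drop = FALSE]
  event_table(x %*% solve(m), rownames(m))
}

#' Write / read a spillover matrix as labeled delimited text
#'
#' @param S A [spillover_matrix()] (for writing).
#' @param path File path.
#' @return `read_spillover` returns a [spillover_matrix()]; the own
#'   channel of each fluorophore is taken as the column with
#'   coefficient 1.
#' @export
write_spillover <- function(S, path) {
  utils::write.csv(as.data.frame(S$matrix), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_spillover
#' @export
read_spillover <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  own <- vapply(rownames(m), function(f)
    colnames(m)[which.min(abs(m[f, ] - 1))], "")
  spillover_matrix(m, own)
}
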