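#' Saltelli sample for Sobol sensitivity indices
#'
#' Builds the N(2d + 2) evaluation points of the Saltelli scheme from a
#' 2d-dimensional Sobol sequence: base matrices A and B (first and last
#' d columns) followed by the radial mixes AB_i (A with column i taken
#' from B) and BA_i (B with column i from A), each of N rows.
#' Deterministic for fixed N and d; N a power of 2 is recommended.
#'
#' @param ranges a [param_ranges()]-style data.frame (d rows)
#' @param N base sample size
#' @return matrix with N(2d + 2) rows in physical units plus attributes
#'   `N` and `d` recording the block structure (row order: A, B,
#'   AB_1..AB_d, BA_1..BA_d)
#' @export
saltelli_sample <- function(ranges, N) {
  d <- nrow(ranges)
  stopifnot(N >= 2, 2 * d <= 32)
  U <- sobol_sequence(N, 2 * d)
  A <- U[, seq_len(d), drop = FALSE]
  B <- U[, d + seq_len(d), drop = FALSE]
  blocks <- list(A, B)
  for (i in seq_len(d)) { M <- A; M[, i] <- B[, i]; blocks[[2 + i]] <- M }
  for (i in seq_len(d)) { M <- B; M[, i] <- A[, i]; blocks[[2 + d + i]] <- M }
  out <- scale_to_ranges(do.call(rbind, blocks), ranges)
  attr(out, "N") <- N
  attr(out, "d") <- d
  out
}

#' First-order and total-effect Sobol indices
#'
#' Evaluates a deterministic function (typically an emulator posterior
#' mean) on a [saltelli_sample()] and estimates per-input first-order
#' (S1) and total-effect (ST) variance-based sensitivity indices with
#' the Saltelli/Jansen Monte-Carlo estimators, averaging the two radial
#' directions.
#'
#' @param fn function taking a matrix of points and returning one value
#'   per row
#' @param samples matrix from [saltelli_sample()]
#' @return data.frame of class `sensitivity_table` with columns `input`,
#'   `S1`, `ST`
#' @export
sobol_indices <- function(fn, samples) {
  N <- attr(samples, "N"); d <- attr(samples, "d")
  stopifnot(!is.null(N), !is.null(d), nrow(samples) == N * (2 * d + 2))
  yall <- fn(samples)
  stopifnot(length(yall) == nrow(samples))
  yA <- yall[seq_len(N)]
  yB <- yall[N + seq_len(N)]
  V <- stats::var(c(yA, yB))
  if (V < .Machine$double.eps * max(1, mean(c(yA, yB))^2))
    stop("constant function: output variance is zero")
  S1 <- ST <- numeric(d)
  for (i in seq_len(d)) {
    yAB <- yall[(1 + i) * N + seq_len(N)]
    yBA <- yall[(1 + d + i) * N + seq_len(N)]
    # Saltelli (2010) first-order estimator, both directions averaged
    s1 <- (mean(yB * (yAB - yA)) + mean(yA * (yBA - yB))) / 2
    # Jansen total-effect estimator, both directions averaged
    st <- (mean((yA - yAB)^2) + mean((yB - yBA)^2)) / 4
    S1[i] <- s1 / V
    ST[i] <- st / V
  }
  out <- data.frame(input = colnames(samples) %||% paste0("x", seq_len(d)),
                    S1 = S1, ST = ST, stringsAsFactors = FALSE)
  class(out) <- c("sensitivity_table", class(out))
  out
}

#' Cross-output parameter ranking
#'
#' Ranks inputs by their importance across all output features: the
#' weight of input i is its maximum total effect over the outputs,
#' normalised so the weights sum to 1. Descending order with a
#' deterministic tie-break by input name.
#'
#' @param tables list of `sensitivity_table` objects (one per output)
#' @return data.frame with `input`, `max_ST`, `weight`, sorted by
#'   decreasing weight
#' @export
rank_parameters <- function(tables) {
  if (inherits(tables, "sensitivity_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  inputs <- tables[[1]]$input
  ST <- vapply(tables, function(tb) tb$ST[match(inputs, tb$input)],
               numeric(length(inputs)))
  ST <- matrix(ST, nrow = length(inputs))
  max_ST <- apply(ST, 1, max)
  weight <- max_ST / sum(max_ST)
  ord <- order(-weight, inputs)
  data.frame(input = inputs[ord], max_ST = max_ST[ord],
             weight = weight[ord], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Global sensitivity analysis of a set of emulators
#'
#' Runs [sobol_indices()] on the posterior mean of each feature emulator
#' over the design box and returns per-output tables plus the
#' cross-output ranking. Emulator uncertainty is not propagated into
#' the indices.
#'
#' @param emulators list of fitted `la_emulator` objects
#' @param ranges design box
#' @param N Saltelli base sample size
#' @return list with `tables` (per output) and `ranking`
#' @export
gsa_emulators <- function(emulators, ranges, N = 1024) {
  samples <- saltelli_sample(ranges, N)
  tables <- lapply(emulators, function(em)
    sobol_indices(function(M) predict_emulator(em, M)$mean, samples))
  list(tables = tables, ranking = rank_parameters(tables))
}
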