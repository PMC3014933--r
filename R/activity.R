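#' Expected number of elements existing by a time point
#'
#' The accumulation curve of a subtype with Gaussian activity: the number of
#' type-j elements present at relative time \code{t} is
#' \code{n_j * pnorm((t - peak_j) / sigma_j)}, monotone from 0 to \code{n_j},
#' with the activity density (its derivative) peaking at \code{peak_j}.
#'
#' @param t Relative time (vectorized).
#' @param peak Activity peak time of the subtype.
#' @param sigma Activity spread (> 0).
#' @param n Genomic copy number of the subtype.
#' @return Expected element count at each \code{t}.
#' @export
tint_eta <- function(t, peak, sigma, n) {
  stopifnot(sigma > 0)
  n * stats::pnorm((t - peak) / sigma)
}

#' Insertion-target probabilities under the Gaussian activity model
#'
#' For an element of type i retroposing at a random moment of its own
#' activity period, the probability of landing in a type-j element is
#' proportional to the number of type-j elements already present. With
#' Gaussian activity densities this marginalizes in closed form: the expected
#' number of preexisting type-j targets seen by a type-i insertion is
#' \code{n_j * pnorm((t_i - t_j) / sqrt(sigma_i^2 + sigma_j^2))}, and the
#' target distribution is the row-normalization of these weights. Insertion
#' into an element of one's own type is a possible target (the diagonal term
#' \code{n_i * pnorm(0) = n_i / 2}), so each row sums to one over the full
#' target set including the diagonal; \code{exclude_self_target} restricts
#' the target set to other types instead.
#'
#' @param peak Numeric vector of activity peak times.
#' @param sigma Numeric vector of activity spreads (> 0).
#' @param n Numeric vector of copy numbers (or target weights; pass
#'   length-weighted copy numbers to model size-biased targeting).
#' @param exclude_self_target Drop the diagonal from the target set and
#'   renormalize rows over other types only.
#' @param log Return log-probabilities.
#' @return K x K matrix \code{q}; \code{q[i, j]} is the probability that a
#'   type-i insertion lands in type j. Rows sum to 1 over the allowed
#'   target set.
#' @export
insertion_probability <- function(peak, sigma, n, exclude_self_target = FALSE,
                                  log = FALSE) {
  K <- length(peak)
  stopifnot(length(sigma) == K, length(n) == K, all(sigma > 0), all(n > 0))
  dt <- outer(peak, peak, "-")                     # t_i - t_j
  pool <- sqrt(outer(sigma^2, sigma^2, "+"))
  lw <- matrix(log(n), K, K, byrow = TRUE) +
    stats::pnorm(dt / pool, log.p = TRUE)
  if (exclude_self_target) diag(lw) <- -Inf
  mx <- apply(lw, 1, max)
  if (any(!is.finite(mx)))
    stop_numeric(paste("all insertion-target weights underflow for at least one",
                       "type; rescale the time units (peaks/spreads)"))
  lz <- mx + log(rowSums(exp(lw - mx)))
  lq <- lw - lz
  if (log) lq else exp(lq)
}

#' Log-likelihood of a TinT matrix under the activity model
#'
#' Product-multinomial over rows: each tallied insertion of type i
#' contributes \code{log q[i, j]} for its host type j, with \code{q} from
#' [insertion_probability()]. Diagonal (self-insertion) counts are excluded
#' unless the matrix was built with \code{include_self = TRUE}, but the
#' diagonal remains in the target set so that empty reverse cells are
#' informative. The global insertion-probability constant cancels in the
#' conditional likelihood and is not a parameter.
#'
#' @param m A \code{tint_matrix} (ideally after [filter_types()]).
#' @param peak,sigma Parameter vectors aligned with \code{m$types}.
#' @param weights Optional target weights; defaults to \code{m$copy_number}.
#' @param exclude_self_target Passed to [insertion_probability()].
#' @return The log-likelihood; \code{-Inf} (with a warning) if a counted
#'   cell has zero probability under the parameters.
#' @export
tint_loglik <- function(m, peak, sigma, weights = NULL,
                        exclude_self_target = FALSE) {
  stopifnot(inherits(m, "tint_matrix"))
  if (is.null(weights)) weights <- m$copy_number
  lq <- insertion_probability(peak, sigma, weights,
                              exclude_self_target = exclude_self_target,
                              log = TRUE)
  counts <- m$counts
  if (!m$include_self) diag(counts) <- 0L
  used <- counts > 0L
  if (any(used & lq == -Inf)) {
    warning("counted cell with zero probability under these parameters")
    return(-Inf)
  }
  sum(counts[used] * lq[used])
}

# central-interval half-width multipliers for the activity density
Z75 <- stats::qnorm(0.875)   # 1.150349
Z95 <- stats::qnorm(0.975)   # 1.959964
Z99 <- stats::qnorm(0.995)   # 2.575829

#' Fit relative activity periods by maximum likelihood
#'
#' Maximizes the product-multinomial likelihood of a TinT matrix over the
#' activity peak times, with per-type spreads tied to genomic copy numbers
#' (\code{sigma_j} proportional to \code{n_j}) as the model prescribes.
#' Derivative-free simplex optimization with seeded multi-start (one
#' heuristic initialization from host/inserted asymmetry plus random
#' restarts), followed by a quasi-Newton polish. The time scale is relative:
#' the likelihood is invariant under a common shift of all peaks, and the
#' gauge is fixed by the copy-number-weighted centering
#' \code{sum(n_j * t_j) = 0}.
#'
#' @param m A \code{tint_matrix}, typically after [filter_types()]. At least
#'   two types are required.
#' @param restarts Number of optimizer starts (first is heuristic).
#' @param seed Integer seed for the random restarts; recorded in the result.
#' @param tol Relative convergence tolerance of the optimizer.
#' @param sigma_mode \code{"scaled"} (default): \code{sigma_j = n_j / max(n)},
#'   i.e. copy-number-proportional spreads with the largest normalized to 1 —
#'   numerically stable and equivalent to \code{"copy_number"}
#'   (\code{sigma_j = n_j}) up to the time-unit gauge. \code{"free"}
#'   additionally estimates a per-type spread (log-parameterized), intended
#'   for exploratory use only.
#' @param exclude_self_target Restrict insertion targets to other types (see
#'   [insertion_probability()]); off by default.
#' @param weights Optional target weights overriding copy numbers.
#' @return An object of class \code{"tint_activity"}: a data frame, sorted
#'   by activity peak (oldest first), with columns \code{type}, \code{peak},
#'   \code{sigma}, \code{lo75}/\code{hi75}, \code{lo95}/\code{hi95},
#'   \code{lo99}/\code{hi99} (central 75/95/99\% intervals of the activity
#'   density, \code{peak +/- z * sigma} with z = 1.150349, 1.959964,
#'   2.575829), \code{normalized_peak} (peak mapped to the display scale on
#'   which the union of 99\% intervals is [0, 1]) and \code{copy_number}.
#'   Attributes: \code{log_lik}, \code{seed}, \code{restarts},
#'   \code{sigma_mode}, \code{gauge}, \code{convergence}.
#' @export
fit_activity <- function(m, restarts = 10, seed = 1L, tol = 1e-8,
                         sigma_mode = c("scaled", "copy_number", "free"),
                         exclude_self_target = FALSE, weights = NULL) {
  stopifnot(inherits(m, "tint_matrix"))
  sigma_mode <- match.arg(sigma_mode)
  K <- length(m$types)
  if (K < 2L)
    stop_data("at least two subtypes are required to fit relative activity periods")
  n <- as.numeric(m$copy_number)
  if (any(n <= 0))
    stop_data("every fitted subtype needs a positive copy number")
  if (is.null(weights)) weights <- n

  sigma0 <- switch(sigma_mode,
                   scaled = n / max(n),
                   copy_number = n,
                   free = n / max(n))
  free_sigma <- sigma_mode == "free"
  sbar <- mean(sigma0)

  counts <- m$counts
  if (!m$include_self) diag(counts) <- 0L

  negll <- function(par) {
    peak <- par[seq_len(K)] * sbar
    sig <- if (free_sigma) exp(par[K + seq_len(K)]) * sigma0 else sigma0
    ll <- tryCatch(
      tint_loglik(m, peak, sig, weights = weights,
                  exclude_self_target = exclude_self_target),
      tint_numeric_error = function(e) -Inf)
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  # heuristic start: subtypes that mostly host are old, those that mostly
  # insert are young; spread ranks over ~3 spread units
  asym <- colSums(counts) - rowSums(counts)
  r <- rank(asym, ties.method = "first")
  t_heur <- 3 * (mean(r) - r) / max(1, K - 1) * 2   # in sbar units
  inits <- list(t_heur)
  rng <- local_rng(as.integer(seed))
  for (i in seq_len(max(0L, restarts - 1L)))
    inits[[i + 1L]] <- rng$rnorm(K, 0, 3)
  if (free_sigma) inits <- lapply(inits, function(x) c(x, rep(0, K)))

  best <- NULL
  conv <- integer(0)
  for (init in inits) {
    o <- stats::optim(init, negll, method = "Nelder-Mead",
                      control = list(maxit = 3000L * K, reltol = tol))
    o <- stats::optim(o$par, negll, method = "Nelder-Mead",
                      control = list(maxit = 3000L * K, reltol = tol))
    o2 <- tryCatch(stats::optim(o$par, negll, method = "BFGS",
                                control = list(maxit = 500L, reltol = tol)),
                   error = function(e) NULL)
    if (!is.null(o2) && is.finite(o2$value) && o2$value < o$value) o <- o2
    conv <- c(conv, o$convergence)
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!is.finite(best$value) || best$value >= 1e12)
    stop_numeric("activity fit failed to find a finite-likelihood optimum")

  peak <- best$par[seq_len(K)] * sbar
  sigma <- if (free_sigma) exp(best$par[K + seq_len(K)]) * sigma0 else sigma0
  peak <- peak - sum(n * peak) / sum(n)     # gauge: copy-number-weighted center

  lo99 <- peak - Z99 * sigma; hi99 <- peak + Z99 * sigma
  span <- range(c(lo99, hi99))
  est <- data.frame(
    type = m$types, peak = peak, sigma = sigma,
    lo75 = peak - Z75 * sigma, hi75 = peak + Z75 * sigma,
    lo95 = peak - Z95 * sigma, hi95 = peak + Z95 * sigma,
    lo99 = lo99, hi99 = hi99,
    normalized_peak = (peak - span[1]) / diff(span),
    copy_number = m$copy_number,
    stringsAsFactors = FALSE
  )
  est <- est[order(est$peak), , drop = FALSE]
  rownames(est) <- NULL
  structure(est,
            class = c("tint_activity", "data.frame"),
            log_lik = -best$value,
            seed = as.integer(seed),
            restarts = as.integer(restarts),
            sigma_mode = sigma_mode,
            gauge = "sum(copy_number * peak) = 0",
            convergence = conv)
}

#' @export
print.tint_activity <- function(x, ...) {
  cat(sprintf("Relative activity periods (%d subtypes, log-likelihood %.4f, oldest first)\n",
              nrow(x), attr(x, "log_lik")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Serialize an activity estimate
#'
#' Tab-separated table (type, peak, sigma, interval bounds, copy number) with
#' a run-metadata header recording seed, restarts, spread mode, gauge and the
#' fitted log-likelihood, so every output carries the parameters that
#' produced it.
#'
#' @param est A \code{tint_activity}.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_activity <- function(est, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(sprintf("# %s=%s",
                     c("seed", "restarts", "sigma_mode", "gauge", "log_lik"),
                     c(attr(est, "seed"), attr(est, "restarts"),
                       attr(est, "sigma_mode"), attr(est, "gauge"),
                       format(attr(est, "log_lik"), digits = 12))), con)
  utils::write.table(as.data.frame(est), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a serialized activity estimate
#'
#' @param file Path written by [write_activity()].
#' @return A \code{tint_activity} data frame (metadata in attributes).
#' @export
read_activity <- function(file) {
  lines <- readLines(file, warn = FALSE)
  meta <- lines[startsWith(lines, "# ")]
  est <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  kv <- sub("^# ", "", meta)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)   # values may themselves contain '='
  get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA
  structure(est, class = c("tint_activity", "data.frame"),
            log_lik = as.numeric(get("log_lik")),
            seed = as.integer(get("seed")),
            restarts = as.integer(get("restarts")),
            sigma_mode = get("sigma_mode"),
            gauge = get("gauge"))
}

# self-contained RNG stream: leaves the caller's .Random.seed untouched
local_rng <- function(seed) {
  state <- NULL
  run <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, globalenv())
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr
  }
  list(
    rnorm = function(...) run(stats::rnorm(...)),
    runif = function(...) run(stats::runif(...)),
    sample = function(...) run(sample(...)),
    rbinom = function(...) run(stats::rbinom(...))
  )
}
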