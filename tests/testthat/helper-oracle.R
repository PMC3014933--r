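# Independent brute-force implementations used as test oracles.
# Deliberately naive (row-by-row loops, no shared code with the package
# internals beyond the public data frames).

# Brute-force application of the five unambiguity criteria. Returns one row
# per (host fragment pair, contained instance), like detect_nested().
oracle_detect <- function(hits, params) {
  out <- list(); nout <- 0L
  for (q in unique(hits$query_id)) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    h <- h[order(h$query_begin, h$query_end), , drop = FALSE]
    n <- nrow(h)
    span_q <- h$query_end - h$query_begin + 1L
    span_c <- h$cons_end - h$cons_begin + 1L

    ids <- unique(h$element_id)
    inst <- list()
    for (id in ids) {
      w <- which(h$element_id == id)
      big <- w[order(-span_q[w], h$query_begin[w])][1]
      inst[[as.character(id)]] <- list(
        id = id, rows = w,
        begin = min(h$query_begin[w]), end = max(h$query_end[w]),
        minspan = min(span_q[w]), type = h$repeat_name[big])
    }

    if (params$use_element_index) {
      pair_list <- list()
      for (id in ids) {
        w <- inst[[as.character(id)]]$rows
        if (length(w) < 2L) next
        for (k in seq_len(length(w) - 1L))
          pair_list[[length(pair_list) + 1L]] <- c(w[k], w[k + 1L])
      }
    } else {
      keyv <- if (params$class_level_match) {
        if (params$class_only) sub("/.*$", "", h$repeat_class) else h$repeat_class
      } else h$repeat_name
      pair_list <- list()
      for (a in seq_len(max(0L, n - 1L))) {
        b <- NA
        for (bb in (a + 1L):n) if (keyv[bb] == keyv[a]) { b <- bb; break }
        if (!is.na(b)) pair_list[[length(pair_list) + 1L]] <- c(a, b)
      }
    }

    for (pr in pair_list) {
      a <- pr[1]; b <- pr[2]
      if (h$query_end[a] >= h$query_begin[b]) next          # fragments overlap on query
      if (h$strand[a] != h$strand[b]) next                  # criterion 4
      if (span_q[a] < params$min_query_length ||
          span_q[b] < params$min_query_length) next         # criterion 3, host side
      ov <- if (h$strand[a] == "+") h$cons_end[a] - h$cons_begin[b] + 1L
            else h$cons_end[b] - h$cons_begin[a] + 1L
      nv1 <- span_c[a] - max(0L, ov); nv2 <- span_c[b] - max(0L, ov)
      pass5 <- (nv1 >= params$min_repeat_extension && nv2 >= params$min_repeat_extension) ||
        (nv1 >= params$min_repeat_extension_overlay &&
           nv2 >= params$min_repeat_extension_overlay &&
           ov <= params$max_repeat_overlay)
      if (!pass5) next                                      # criterion 5
      host_id <- h$element_id[a]
      host_type <- if (params$use_element_index) inst[[as.character(host_id)]]$type
                   else h$repeat_name[if (span_q[b] > span_q[a]) b else a]
      for (x in inst) {
        if (!(x$begin > h$query_end[a] && x$end < h$query_begin[b])) next  # criterion 1
        if (params$use_element_index && !(x$id > host_id)) next            # criterion 2
        if (x$minspan < params$min_query_length) next       # criterion 3, inserted side
        nout <- nout + 1L
        out[[nout]] <- data.frame(query_id = q, inserted_id = x$id,
                                  host_id = host_id,
                                  inserted_type = x$type, host_type = host_type,
                                  gap_begin = h$query_end[a],
                                  gap_end = h$query_begin[b],
                                  stringsAsFactors = FALSE)
      }
    }
  }
  if (nout) do.call(rbind, out) else
    data.frame(query_id = character(), inserted_id = integer(),
               host_id = integer(), inserted_type = character(),
               host_type = character(), gap_begin = integer(),
               gap_end = integer(), stringsAsFactors = FALSE)
}

event_key <- function(ev) {
  if (nrow(ev) == 0L) return(character())
  sort(paste(ev$query_id, ev$inserted_id, ev$gap_begin, ev$gap_end, sep = "|"))
}

# Target distribution by adaptive quadrature of the defining integral
# q_ij  proportional to  integral dnorm(tau; t_i, s_i) * n_j * pnorm((tau - t_j)/s_j) dtau
oracle_q <- function(peak, sigma, n, exclude_self = FALSE) {
  K <- length(peak)
  num <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    num[i, j] <- stats::integrate(function(tau)
      stats::dnorm(tau, peak[i], sigma[i]) * n[j] * stats::pnorm((tau - peak[j]) / sigma[j]),
      lower = peak[i] - 10 * sigma[i], upper = peak[i] + 10 * sigma[i],
      rel.tol = 1e-11, abs.tol = 0)$value
  }
  if (exclude_self) diag(num) <- 0
  num / rowSums(num)
}

# Expected detectable event set from the simulator's ground-truth ledger:
# walk each true nesting up the chain of enclosing hosts to the first
# ancestor whose flanking fragment pair passes criteria (3)/(5); this mirrors
# innermost attribution from the truth side without consulting the detector.
oracle_closure <- function(sim, params) {
  hits <- sim$hits; truth <- sim$truth; inst <- sim$instances
  parent <- stats::setNames(truth$host_uid, as.character(truth$inserted_uid))
  irow <- stats::setNames(seq_len(nrow(inst)), as.character(inst$uid))
  span_q <- hits$query_end - hits$query_begin + 1L
  span_c <- hits$cons_end - hits$cons_begin + 1L

  frag_rows <- function(uid) {
    i <- irow[[as.character(uid)]]
    which(hits$query_id == inst$query_id[i] & hits$element_id == inst$element_id[i])
  }
  range_of <- function(uid) {
    w <- frag_rows(uid)
    c(min(hits$query_begin[w]), max(hits$query_end[w]))
  }
  pair_passes <- function(x_uid, h_uid) {
    xr <- range_of(x_uid)
    w <- frag_rows(h_uid)
    left <- w[hits$query_end[w] < xr[1]]
    right <- w[hits$query_begin[w] > xr[2]]
    if (!length(left) || !length(right)) return(FALSE)
    a <- left[which.max(hits$query_end[left])]
    b <- right[which.min(hits$query_begin[right])]
    if (hits$strand[a] != hits$strand[b]) return(FALSE)
    if (span_q[a] < params$min_query_length ||
        span_q[b] < params$min_query_length) return(FALSE)
    ov <- if (hits$strand[a] == "+") hits$cons_end[a] - hits$cons_begin[b] + 1L
          else hits$cons_end[b] - hits$cons_begin[a] + 1L
    nv1 <- span_c[a] - max(0L, ov); nv2 <- span_c[b] - max(0L, ov)
    (nv1 >= params$min_repeat_extension && nv2 >= params$min_repeat_extension) ||
      (nv1 >= params$min_repeat_extension_overlay &&
         nv2 >= params$min_repeat_extension_overlay &&
         ov <= params$max_repeat_overlay)
  }

  out <- list(); nout <- 0L
  for (k in seq_len(nrow(truth))) {
    x <- truth$inserted_uid[k]
    w <- frag_rows(x)
    if (min(span_q[w]) < params$min_query_length) next  # inserted fails criterion 3
    anc <- truth$host_uid[k]
    while (!is.na(anc)) {
      if (pair_passes(x, anc)) {
        nout <- nout + 1L
        out[[nout]] <- data.frame(
          inserted_uid = x, host_uid = anc,
          query_id = inst$query_id[irow[[as.character(x)]]],
          inserted_id = inst$element_id[irow[[as.character(x)]]],
          host_id = inst$element_id[irow[[as.character(anc)]]],
          inserted_type = inst$type[irow[[as.character(x)]]],
          host_type = inst$type[irow[[as.character(anc)]]],
          stringsAsFactors = FALSE)
        break
      }
      anc <- if (as.character(anc) %in% names(parent)) parent[[as.character(anc)]] else NA
    }
  }
  if (nout) do.call(rbind, out) else
    data.frame(inserted_uid = integer(), host_uid = integer(),
               query_id = character(), inserted_id = integer(),
               host_id = integer(), inserted_type = character(),
               host_type = character(), stringsAsFactors = FALSE)
}
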