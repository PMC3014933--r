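#' Configuration for the nested-retroposition simulator
#'
#' Describes a forward simulation of retroposon proliferation with known
#' ground truth. Each subtype has a Gaussian activity window (peak and
#' spread on an arbitrary relative scale), a copy number and a consensus
#' length. Elements insert in time order at positions drawn uniformly over
#' the current genome length (background plus accumulated elements), so a
#' subtype attracts hits in proportion to its accumulated length — including
#' the size bias that makes long elements preferred targets. A hit inside an
#' element fragments the host into two records sharing an element ID whose
#' consensus coordinates overlap by the target-site-duplication length.
#'
#' The default scenario is six Alu-like subfamilies on one activity
#' succession: equal copy numbers (800), equal spreads, peaks two spread
#' units apart (well-separated), 300-nt consensus (dimeric-Alu scale), and a
#' 12-nt TSD (typical L1-machinery scale, safely below the 35-nt overlay
#' threshold). The genome is emitted as many short query sequences, matching
#' trace-data usage.
#'
#' @param types Data frame with columns \code{name}, \code{class},
#'   \code{copy_number}, \code{peak}, \code{sigma}, \code{consensus_length}.
#' @param genome_background Total non-element sequence, nt, split evenly
#'   across loci.
#' @param n_loci Number of query sequences to distribute elements over.
#' @param tsd_length Target-site-duplication length, nt; drives the
#'   consensus overlap of host fragment pairs.
#' @param min_fragment Smallest host fragment the simulator will emit, nt;
#'   insertions that would create a smaller fragment are retried at a fresh
#'   landing point.
#' @param seed Integer seed; identical configurations give byte-identical
#'   output.
#' @param misannotation_rate Probability that an emitted fragment's subtype
#'   name is swapped for another subtype of the same class.
#' @param id_loss_rate Probability that a fragmented element is emitted with
#'   distinct IDs per fragment (defeats stringent pairing, not relaxed).
#' @return An object of class \code{"tint_sim_config"}.
#' @export
simulation_config <- function(types = default_sim_types(),
                              genome_background = 120000,
                              n_loci = 400,
                              tsd_length = 12,
                              min_fragment = 15,
                              seed = 1L,
                              misannotation_rate = 0,
                              id_loss_rate = 0) {
  req <- c("name", "class", "copy_number", "peak", "sigma", "consensus_length")
  if (!is.data.frame(types) || !all(req %in% names(types)))
    stop_config(sprintf("simulation types must be a data frame with columns %s",
                        paste(req, collapse = ", ")))
  if (any(types$copy_number < 0))
    stop_config("copy numbers must be non-negative")
  if (any(types$sigma <= 0))
    stop_config("activity spreads must be positive")
  if (any(types$consensus_length < 2 * min_fragment))
    stop_config("consensus_length must be at least 2 * min_fragment")
  if (misannotation_rate < 0 || misannotation_rate > 1 ||
      id_loss_rate < 0 || id_loss_rate > 1)
    stop_config("noise rates must lie in [0, 1]")
  if (tsd_length < 0 || min_fragment <= tsd_length)
    stop_config("min_fragment must exceed tsd_length (and tsd_length be >= 0)")
  structure(list(types = types, genome_background = genome_background,
                 n_loci = as.integer(n_loci), tsd_length = as.integer(tsd_length),
                 min_fragment = as.integer(min_fragment), seed = as.integer(seed),
                 misannotation_rate = misannotation_rate,
                 id_loss_rate = id_loss_rate),
            class = "tint_sim_config")
}

#' @rdname simulation_config
#' @export
default_sim_types <- function() {
  data.frame(
    name = c("AluJo", "AluJb", "AluSx", "AluSq", "AluSp", "AluY"),
    class = "SINE/Alu",
    copy_number = 800L,
    peak = c(0, 2, 4, 6, 8, 10),
    sigma = 1,
    consensus_length = 300L,
    stringsAsFactors = FALSE
  )
}

#' Forward-simulate nested retroposition
#'
#' Draws per-element insertion times from each subtype's Gaussian activity
#' window, processes insertions in time order with uniform landing over the
#' current genome, fragments hit hosts with TSD-induced consensus overlap,
#' and emits the result as RepeatMasker-style annotation records plus a
#' ground-truth ledger of every element-in-element landing.
#'
#' @param config A [simulation_config()].
#' @return A list with elements \code{hits} (annotation data frame accepted
#'   by [write_rm_out()] and [detect_tints()]), \code{truth} (data frame of
#'   true nestings: \code{inserted_uid}, \code{host_uid},
#'   \code{inserted_type}, \code{host_type}, \code{query_id}, \code{time}),
#'   \code{instances} (one row per simulated element: \code{uid},
#'   \code{query_id}, \code{element_id}, \code{type}, \code{n_fragments})
#'   and \code{config}.
#' @export
simulate_tints <- function(config) {
  stopifnot(inherits(config, "tint_sim_config"))
  rng <- local_rng(config$seed)
  ty <- config$types
  K <- nrow(ty)

  times <- numeric(0); tix <- integer(0)
  for (j in seq_len(K)) {
    if (ty$copy_number[j] == 0) next
    tj <- rng$rnorm(ty$copy_number[j], ty$peak[j], ty$sigma[j])
    times <- c(times, tj)
    tix <- c(tix, rep.int(j, ty$copy_number[j]))
  }
  ord <- order(times)
  times <- times[ord]; tix <- tix[ord]
  N <- length(times)

  nl <- config$n_loci
  bg <- rep.int(config$genome_background %/% nl, nl)
  if (config$genome_background %% nl) bg[seq_len(config$genome_background %% nl)] <-
    bg[seq_len(config$genome_background %% nl)] + 1L

  # per-locus parallel vectors of genome pieces; uid 0 = background
  loci <- lapply(bg, function(b)
    list(uid = 0L, type = 0L, strand = 1L, cb = 0L, ce = 0L, len = as.integer(b)))
  locus_len <- as.numeric(bg)

  el_type <- integer(N); el_locus <- integer(N); el_strand <- integer(N)
  ev_ins <- integer(0); ev_host <- integer(0); ev_time <- numeric(0)
  tsd <- config$tsd_length; minf <- config$min_fragment

  for (e in seq_len(N)) {
    j <- tix[e]
    clen <- ty$consensus_length[j]
    strand <- rng$sample(1:2, 1L)
    placed <- FALSE
    for (try in 1:200) {
      u <- rng$runif(1, 0, sum(locus_len))
      cs <- cumsum(locus_len)
      l <- which(cs >= u)[1]
      pos <- u - c(0, cs)[l]
      L <- loci[[l]]
      pc <- cumsum(L$len)
      p <- which(pc >= pos)[1]
      d <- pos - c(0, pc)[p]

      newpiece <- list(uid = e, type = j, strand = strand,
                       cb = 1L, ce = as.integer(clen), len = as.integer(clen))
      if (L$uid[p] == 0L) {
        dl <- as.integer(floor(d))
        dr <- L$len[p] - dl
        left <- list(uid = 0L, type = 0L, strand = 1L, cb = 0L, ce = 0L, len = dl)
        right <- list(uid = 0L, type = 0L, strand = 1L, cb = 0L, ce = 0L, len = dr)
        loci[[l]] <- splice_piece(L, p, left, newpiece, right)
        placed <- TRUE
      } else {
        dl <- as.integer(round(d))
        plen <- L$len[p]
        if (dl < minf || plen - dl < minf || dl <= tsd) next
        host_uid <- L$uid[p]
        if (L$strand[p] == 1L) {           # plus-strand host
          left <- list(uid = host_uid, type = L$type[p], strand = 1L,
                       cb = L$cb[p], ce = L$cb[p] + dl - 1L, len = dl)
          right <- list(uid = host_uid, type = L$type[p], strand = 1L,
                        cb = L$cb[p] + dl - tsd, ce = L$ce[p],
                        len = L$ce[p] - (L$cb[p] + dl - tsd) + 1L)
        } else {                            # complement: left query part = consensus tail
          left <- list(uid = host_uid, type = L$type[p], strand = 2L,
                       cb = L$ce[p] - dl + 1L, ce = L$ce[p], len = dl)
          right <- list(uid = host_uid, type = L$type[p], strand = 2L,
                        cb = L$cb[p], ce = L$ce[p] - dl + tsd,
                        len = (L$ce[p] - dl + tsd) - L$cb[p] + 1L)
        }
        loci[[l]] <- splice_piece(L, p, left, newpiece, right)
        ev_ins <- c(ev_ins, e); ev_host <- c(ev_host, host_uid)
        ev_time <- c(ev_time, times[e])
        placed <- TRUE
      }
      if (placed) {
        el_type[e] <- j; el_locus[e] <- l; el_strand[e] <- strand
        locus_len[l] <- locus_len[l] + clen + if (L$uid[p] != 0L) tsd else 0L
        break
      }
    }
    if (!placed)
      stop_numeric("simulator could not place an insertion after 200 retries; enlarge the genome or loosen min_fragment")
  }

  emit_simulation(config, loci, el_type, el_locus, rng,
                  ev_ins, ev_host, ev_time, times)
}

splice_piece <- function(L, p, left, mid, right) {
  n <- length(L$len)
  pre <- if (p > 1L) seq_len(p - 1L) else integer(0)
  post <- if (p < n) (p + 1L):n else integer(0)
  out <- list()
  for (f in names(L)) {
    parts <- c(L[[f]][pre], left[[f]], mid[[f]], right[[f]], L[[f]][post])
    out[[f]] <- parts
  }
  # drop zero-length background slivers
  keep <- out$len > 0L
  lapply(out, `[`, keep)
}

emit_simulation <- function(config, loci, el_type, el_locus, rng,
                            ev_ins, ev_host, ev_time, times) {
  ty <- config$types
  qid_of <- function(l) sprintf("sim_locus_%04d", l)

  rows <- list(); nr <- 0L
  uid_col <- integer(0)
  id_map_all <- list()
  for (l in seq_along(loci)) {
    L <- loci[[l]]
    el <- which(L$uid > 0L)
    if (!length(el)) next
    qe <- cumsum(L$len)
    qb <- qe - L$len + 1L
    total <- qe[length(qe)]
    uids <- L$uid[el]
    ids <- match(uids, unique(uids))     # IDs by order of first appearance
    id_map_all[[qid_of(l)]] <- stats::setNames(ids, uids)
    tjx <- L$type[el]
    span <- L$len[el]
    nr <- nr + 1L
    rows[[nr]] <- data.frame(
      sw_score = as.integer(round(span * 8.2)),
      pct_div = round(6 + 1.7 * tjx, 1),
      pct_del = 1.1, pct_ins = 0.8,
      query_id = qid_of(l),
      query_begin = as.integer(qb[el]),
      query_end = as.integer(qe[el]),
      query_left = as.integer(total - qe[el]),
      strand = c("+", "C")[L$strand[el]],
      repeat_name = ty$name[tjx],
      repeat_class = ty$class[tjx],
      cons_begin = as.integer(L$cb[el]),
      cons_end = as.integer(L$ce[el]),
      cons_left = as.integer(ty$consensus_length[tjx] - L$ce[el]),
      element_id = as.integer(ids),
      overlap_flag = FALSE,
      stringsAsFactors = FALSE
    )
    uid_col <- c(uid_col, uids)
  }
  hits <- if (nr) do.call(rbind, rows) else empty_hits()
  rownames(hits) <- NULL

  # noise: subtype misannotation within class
  if (config$misannotation_rate > 0 && nrow(hits)) {
    flip <- rng$runif(nrow(hits)) < config$misannotation_rate
    for (i in which(flip)) {
      same <- which(ty$class == ty$class[el_type[uid_col[i]]] &
                      ty$name != hits$repeat_name[i])
      if (length(same)) {
        k <- same[rng$sample(length(same), 1L)]
        hits$repeat_name[i] <- ty$name[k]
        hits$cons_left[i] <- as.integer(ty$consensus_length[k] - hits$cons_end[i])
      }
    }
  }
  # noise: fragmented hosts emitted with distinct IDs
  if (config$id_loss_rate > 0 && nrow(hits)) {
    for (q in unique(hits$query_id)) {
      qi <- which(hits$query_id == q)
      next_id <- max(hits$element_id[qi]) + 1L
      for (u in unique(uid_col[qi])) {
        fr <- qi[uid_col[qi] == u]
        if (length(fr) >= 2L && rng$runif(1) < config$id_loss_rate) {
          hits$element_id[fr] <- next_id + seq_along(fr) - 1L
          next_id <- next_id + length(fr)
        }
      }
    }
  }

  placed <- which(el_locus > 0L)
  inst <- data.frame(
    uid = placed,
    query_id = qid_of(el_locus[placed]),
    type = ty$name[el_type[placed]],
    time = times[placed],
    stringsAsFactors = FALSE
  )
  inst$element_id <- vapply(seq_len(nrow(inst)), function(i) {
    mp <- id_map_all[[inst$query_id[i]]]
    as.integer(mp[as.character(inst$uid[i])])
  }, integer(1))
  frag_tab <- table(uid_col)
  inst$n_fragments <- as.integer(frag_tab[as.character(inst$uid)])

  truth <- data.frame(
    inserted_uid = ev_ins,
    host_uid = ev_host,
    inserted_type = ty$name[el_type[ev_ins]],
    host_type = ty$name[el_type[ev_host]],
    query_id = qid_of(el_locus[ev_ins]),
    time = ev_time,
    stringsAsFactors = FALSE
  )

  list(hits = hits, truth = truth, instances = inst, config = config)
}

#' Expected insertion-count matrix for a simulation scenario
#'
#' Analytic twin of [simulate_tints()] for validation: the expected share of
#' type-i insertions landing in type j under the closed-form target
#' distribution of [insertion_probability()], with target weights
#' proportional to copy number times consensus length (the simulator's
#' landing rule is uniform per nucleotide, so long subtypes attract
#' proportionally more hits). Multiplied by the number of tallied type-i
#' insertions to give expected cell counts.
#'
#' @param config A [simulation_config()].
#' @param n_events Numeric vector (length K, aligned with
#'   \code{config$types}) of tallied insertions per inserted type, e.g. the
#'   row totals of an observed matrix. Defaults to the copy numbers (every
#'   insertion tallied), an upper-bound scenario useful for shape checks.
#' @param exclude_self_target Passed to [insertion_probability()].
#' @return Matrix of expected counts (rows = inserted, cols = host).
#' @export
expected_matrix <- function(config, n_events = NULL,
                            exclude_self_target = FALSE) {
  stopifnot(inherits(config, "tint_sim_config"))
  ty <- config$types
  if (is.null(n_events)) n_events <- ty$copy_number
  stopifnot(length(n_events) == nrow(ty))
  q <- insertion_probability(ty$peak, ty$sigma,
                             n = ty$copy_number * ty$consensus_length,
                             exclude_self_target = exclude_self_target)
  out <- q * n_events
  dimnames(out) <- list(inserted = ty$name, host = ty$name)
  out
}

#' Write the simulator's ground-truth ledger
#'
#' Tab-separated event ledger (one true element-in-element landing per row)
#' plus the generating parameters as a companion table.
#'
#' @param sim Result of [simulate_tints()].
#' @param events_file,params_file Output paths.
#' @return Invisibly, `events_file`.
#' @export
write_ground_truth <- function(sim, events_file, params_file = NULL) {
  utils::write.table(sim$truth, events_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(params_file))
    utils::write.table(sim$config$types, params_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(events_file)
}

#' Read a simulator configuration file
#'
#' Plain key-value format: scalar fields as \code{key = value} lines and one
#' \code{type = name class copy_number peak sigma consensus_length} line per
#' subtype. Lines starting with \code{#} are ignored.
#'
#' @param file Path to the configuration file.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad))
    stop_config(sprintf("malformed simulator config line: %s", lines[bad[1]]))
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)

  trows <- which(keys == "type")
  if (!length(trows))
    stop_config("simulator config field 'type' missing: at least one subtype line is required")
  tparts <- strsplit(trimws(vals[trows]), "\\s+")
  if (any(lengths(tparts) != 6L))
    stop_config("field 'type' must have 6 entries: name class copy_number peak sigma consensus_length")
  tp <- do.call(rbind, tparts)
  types <- data.frame(name = tp[, 1], class = tp[, 2],
                      copy_number = as.integer(tp[, 3]),
                      peak = as.numeric(tp[, 4]), sigma = as.numeric(tp[, 5]),
                      consensus_length = as.integer(tp[, 6]),
                      stringsAsFactors = FALSE)
  if (anyNA(types))
    stop_config("field 'type' contains a non-numeric value where a number is required")

  num <- function(key, default) {
    i <- match(key, keys)
    if (is.na(i)) return(default)
    v <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(v)) stop_config(sprintf("field '%s' must be numeric, got '%s'", key, vals[i]))
    v
  }
  simulation_config(
    types = types,
    genome_background = num("genome_background", 120000),
    n_loci = num("n_loci", 400),
    tsd_length = num("tsd_length", 12),
    min_fragment = num("min_fragment", 15),
    seed = num("seed", 1),
    misannotation_rate = num("misannotation_rate", 0),
    id_loss_rate = num("id_loss_rate", 0)
  )
}
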