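#' Detection thresholds for unambiguous nested insertions
#'
#' Bundles the tunable thresholds of the five unambiguity criteria used to
#' accept a nested insertion, with the empirically optimized defaults:
#'
#' \enumerate{
#'   \item inserted and interrupted elements lie on the same query sequence;
#'   \item (stringent mode) the two host fragments carry identical element
#'     indices and the inserted element's index is higher; in relaxed mode
#'     indices are ignored and the host fragments need only share a subtype
#'     (or class);
#'   \item every fragment spans at least \code{min_query_length} nt on the
#'     query (default 20);
#'   \item both host fragments have the same orientation;
#'   \item the host's consensus sequence is continuous across the break:
#'     each fragment's non-overlapping consensus span is preferably at least
#'     \code{min_repeat_extension} nt (default 50), or at least
#'     \code{min_repeat_extension_overlay} nt (default 18) with a consensus
#'     overlap of at most \code{max_repeat_overlay} nt (default 35).
#'     Overlaps arise from target site duplications or low-complexity
#'     regions.
#' }
#'
#' @param min_query_length Minimal query length, nt.
#' @param min_repeat_extension Minimal repeat extension, nt.
#' @param min_repeat_extension_overlay Minimal repeat extension overlay, nt.
#' @param max_repeat_overlay Maximal repeat overlay, nt.
#' @param use_element_index Stringent mode: pair host fragments by shared
#'   element index and require the inserted index to be higher. \code{FALSE}
#'   selects relaxed mode, recommended only when data are scarce.
#' @param class_level_match Relaxed mode only: pair host fragments by
#'   repeat class instead of subtype name.
#' @param class_only When matching by class, compare only the part before
#'   the first \code{"/"} (e.g. \code{"SINE"}) instead of the full
#'   class/family string (e.g. \code{"SINE/Alu"}).
#' @return An object of class \code{"tint_params"} (a named list).
#' @export
detection_params <- function(min_query_length = 20,
                             min_repeat_extension = 50,
                             min_repeat_extension_overlay = 18,
                             max_repeat_overlay = 35,
                             use_element_index = TRUE,
                             class_level_match = FALSE,
                             class_only = FALSE) {
  if (min_query_length <= 0 || min_repeat_extension <= 0 ||
      min_repeat_extension_overlay <= 0)
    stop_config("detection length thresholds must be positive")
  if (min_repeat_extension < min_repeat_extension_overlay)
    stop_config("min_repeat_extension must be >= min_repeat_extension_overlay")
  structure(list(
    min_query_length = min_query_length,
    min_repeat_extension = min_repeat_extension,
    min_repeat_extension_overlay = min_repeat_extension_overlay,
    max_repeat_overlay = max_repeat_overlay,
    use_element_index = isTRUE(use_element_index),
    class_level_match = isTRUE(class_level_match),
    class_only = isTRUE(class_only)
  ), class = "tint_params")
}

empty_events <- function() {
  data.frame(query_id = character(), inserted_id = integer(), host_id = integer(),
             inserted_type = character(), host_type = character(),
             inserted_begin = integer(), inserted_end = integer(),
             gap_begin = integer(), gap_end = integer(),
             consensus_overlap = integer(), strand = character(),
             self_insertion = logical(), stringsAsFactors = FALSE)
}

# consensus overlap of a host fragment pair; f1 is upstream on the query.
# On the plus strand f1 carries the upstream consensus segment; on the
# complement strand the roles are mirrored in consensus orientation.
pair_overlap <- function(hits, i1, i2) {
  if (hits$strand[i1] == "+")
    hits$cons_end[i1] - hits$cons_begin[i2] + 1L
  else
    hits$cons_end[i2] - hits$cons_begin[i1] + 1L
}

# criterion 5: consensus continuity of a host fragment pair
pass_continuity <- function(hits, i1, i2, params) {
  ov <- pair_overlap(hits, i1, i2)
  span1 <- hits$cons_end[i1] - hits$cons_begin[i1] + 1L
  span2 <- hits$cons_end[i2] - hits$cons_begin[i2] + 1L
  non1 <- span1 - max(0L, ov)
  non2 <- span2 - max(0L, ov)
  ok <- (non1 >= params$min_repeat_extension && non2 >= params$min_repeat_extension) ||
    (non1 >= params$min_repeat_extension_overlay &&
       non2 >= params$min_repeat_extension_overlay &&
       ov <= params$max_repeat_overlay)
  list(ok = ok, overlap = ov)
}

#' Detect unambiguously nested insertions
#'
#' Applies the five unambiguity criteria (see [detection_params()]) to all
#' candidate host fragment pairs of each query sequence and emits one event
#' per (host context, contained element instance). Single elements, which
#' neither inserted into another element nor were fragmented, produce no
#' events. Multi-level nests yield an event for every enclosing context
#' here; use [detect_tints()] for innermost attribution, which is what the
#' counting pipeline uses.
#'
#' @param hits Data frame from [read_rm_out()].
#' @param params A [detection_params()] object.
#' @return A data frame of accepted events with columns \code{query_id},
#'   \code{inserted_id}, \code{host_id}, \code{inserted_type},
#'   \code{host_type}, \code{inserted_begin}, \code{inserted_end},
#'   \code{gap_begin}, \code{gap_end} (the open query interval between the
#'   host fragments), \code{consensus_overlap}, \code{strand} and
#'   \code{self_insertion} (inserted and host subtype identical). The
#'   attribute \code{"diagnostics"} holds per-query candidate-pair counts
#'   and rejection tallies keyed by criterion.
#' @export
detect_nested <- function(hits, params = detection_params()) {
  stopifnot(inherits(params, "tint_params"))
  instances <- group_elements(hits)
  if (nrow(hits) == 0L) {
    ev <- empty_events()
    attr(ev, "diagnostics") <- empty_diagnostics()
    return(ev)
  }

  res <- list(); nres <- 0L
  diags <- list()

  for (qid in unique(hits$query_id)) {
    inst_q <- instances[instances$query_id == qid, , drop = FALSE]
    d <- c(pairs_candidate = 0L, rej_query_overlap = 0L, rej_strand = 0L,
           rej_query_length = 0L, rej_consensus = 0L, accepted_pairs = 0L)

    pairs <- host_pairs(hits, inst_q, params)
    for (p in pairs) {
      i1 <- p$i1; i2 <- p$i2
      d["pairs_candidate"] <- d["pairs_candidate"] + 1L
      if (hits$query_end[i1] >= hits$query_begin[i2]) {
        d["rej_query_overlap"] <- d["rej_query_overlap"] + 1L; next
      }
      if (hits$strand[i1] != hits$strand[i2]) {                       # criterion 4
        d["rej_strand"] <- d["rej_strand"] + 1L; next
      }
      span1 <- hits$query_end[i1] - hits$query_begin[i1] + 1L
      span2 <- hits$query_end[i2] - hits$query_begin[i2] + 1L
      if (span1 < params$min_query_length || span2 < params$min_query_length) {  # criterion 3 (host)
        d["rej_query_length"] <- d["rej_query_length"] + 1L; next
      }
      cont <- pass_continuity(hits, i1, i2, params)                    # criterion 5
      if (!cont$ok) {
        d["rej_consensus"] <- d["rej_consensus"] + 1L; next
      }
      d["accepted_pairs"] <- d["accepted_pairs"] + 1L

      g1 <- hits$query_end[i1]; g2 <- hits$query_begin[i2]
      # the host instance itself extends beyond the gap on both sides, so it
      # can never satisfy strict containment; no explicit exclusion needed
      inside <- inst_q$query_begin > g1 & inst_q$query_end < g2
      if (params$use_element_index)
        inside <- inside & inst_q$element_id > p$host_id               # criterion 2
      inside <- inside & inst_q$min_fragment_span >= params$min_query_length  # criterion 3 (inserted)

      for (k in which(inside)) {
        nres <- nres + 1L
        res[[nres]] <- data.frame(
          query_id = qid,
          inserted_id = inst_q$element_id[k],
          host_id = p$host_id,
          inserted_type = inst_q$type[k],
          host_type = p$host_type,
          inserted_begin = inst_q$query_begin[k],
          inserted_end = inst_q$query_end[k],
          gap_begin = g1, gap_end = g2,
          consensus_overlap = cont$overlap,
          strand = hits$strand[i1],
          self_insertion = inst_q$type[k] == p$host_type,
          stringsAsFactors = FALSE
        )
      }
    }
    diags[[qid]] <- d
  }

  ev <- if (nres) do.call(rbind, res) else empty_events()
  rownames(ev) <- NULL
  dd <- if (length(diags)) {
    out <- data.frame(query_id = names(diags), stringsAsFactors = FALSE)
    cbind(out, do.call(rbind, unname(diags)))
  } else empty_diagnostics()
  rownames(dd) <- NULL
  attr(ev, "diagnostics") <- dd
  ev
}

empty_diagnostics <- function() {
  data.frame(query_id = character(), pairs_candidate = integer(),
             rej_query_overlap = integer(), rej_strand = integer(),
             rej_query_length = integer(), rej_consensus = integer(),
             accepted_pairs = integer(), stringsAsFactors = FALSE)
}

# enumerate candidate host fragment pairs on one query sequence.
# Stringent mode: consecutive fragments of one instance (shared element ID).
# Relaxed mode: each fragment paired with the next fragment of the same
# subtype (or class), element IDs ignored.
host_pairs <- function(hits, inst_q, params) {
  pairs <- list(); np <- 0L
  span <- hits$query_end - hits$query_begin + 1L
  if (params$use_element_index) {
    for (ii in seq_len(nrow(inst_q))) {
      fr <- inst_q$fragments[[ii]]
      if (length(fr) < 2L) next
      for (j in seq_len(length(fr) - 1L)) {
        np <- np + 1L
        pairs[[np]] <- list(i1 = fr[j], i2 = fr[j + 1L],
                            host_id = inst_q$element_id[ii],
                            host_type = inst_q$type[ii],
                            host_inst = ii)
      }
    }
  } else {
    rows <- which(hits$query_id == inst_q$query_id[1])
    if (length(rows) < 2L) return(pairs)
    rows <- rows[order(hits$query_begin[rows])]
    key <- if (params$class_level_match) {
      cls <- hits$repeat_class[rows]
      if (params$class_only) sub("/.*$", "", cls) else cls
    } else hits$repeat_name[rows]
    for (a in seq_len(length(rows) - 1L)) {
      b <- a + 1L
      while (b <= length(rows) && key[b] != key[a]) b <- b + 1L
      if (b > length(rows)) next
      i1 <- rows[a]; i2 <- rows[b]
      larger <- if (span[i2] > span[i1]) i2 else i1
      np <- np + 1L
      pairs[[np]] <- list(i1 = i1, i2 = i2,
                          host_id = hits$element_id[i1],
                          host_type = hits$repeat_name[larger],
                          host_inst = NA_integer_)
    }
  }
  pairs
}

#' Detect nested insertions with innermost attribution
#'
#' In multi-level nests (A inside B inside C), [detect_nested()] reports A
#' against every enclosing accepted host context. This wrapper attributes
#' each inserted element instance to its innermost enclosing context — the
#' smallest accepted gap containing it — so the chain A-in-B-in-C yields
#' exactly the events A into B and B into C. This is the event set tallied
#' into the count matrix.
#'
#' @inheritParams detect_nested
#' @return As [detect_nested()], at most one event per inserted instance.
#' @export
detect_tints <- function(hits, params = detection_params()) {
  ev <- detect_nested(hits, params)
  if (nrow(ev) == 0L) return(ev)
  width <- ev$gap_end - ev$gap_begin
  key <- paste(ev$query_id, ev$inserted_id, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(ev)), key), function(i) {
    i[which.min(width[i])]
  }), use.names = FALSE)
  out <- ev[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "diagnostics") <- attr(ev, "diagnostics")
  out
}

#' Write a detection diagnostics report
#'
#' Tab-separated per-query report of candidate host pairs and rejection
#' counts keyed by criterion, as attached to the result of
#' [detect_nested()]/[detect_tints()].
#'
#' @param events Event data frame carrying a \code{"diagnostics"} attribute.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_diagnostics <- function(events, file) {
  d <- attr(events, "diagnostics")
  if (is.null(d)) d <- empty_diagnostics()
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
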