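#' Read a RepeatMasker annotation report (.out file)
#'
#' Parses the standard whitespace-delimited RepeatMasker report into one row
#' per annotation hit. Consensus coordinates of complement-strand hits, which
#' RepeatMasker prints in reversed order as \code{(left) end begin}, are
#' normalized so that \code{cons_begin <= cons_end} for every row; all
#' coordinates are kept 1-based inclusive throughout the package.
#'
#' @param file Path to a RepeatMasker \code{.out} file, or a connection.
#'   Up to three leading header lines and any blank lines are tolerated.
#' @return A data frame with one row per annotation and columns
#'   \code{sw_score}, \code{pct_div}, \code{pct_del}, \code{pct_ins},
#'   \code{query_id}, \code{query_begin}, \code{query_end}, \code{query_left},
#'   \code{strand} (\code{"+"} or \code{"C"}), \code{repeat_name},
#'   \code{repeat_class}, \code{cons_begin}, \code{cons_end}, \code{cons_left},
#'   \code{element_id} and \code{overlap_flag}. Row order follows the file.
#' @details The ID column is required: fragments of one interrupted element
#'   share an ID, and the detection criteria compare these indices. Files
#'   written by RepeatMasker runs without IDs are rejected with instructions
#'   to rerun.
#' @seealso [write_rm_out()], [group_elements()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".out")
#' sim <- simulate_tints(simulation_config(seed = 1))
#' write_rm_out(sim$hits, f)
#' hits <- read_rm_out(f)
#' nrow(hits)
read_rm_out <- function(file) {
  lines <- readLines(file, warn = FALSE)
  n <- length(lines)
  is_blank <- !nzchar(trimws(lines))
  # up to 3 leading header lines: skipped when they do not start with a score
  first_tok_numeric <- function(x) {
    tok <- sub("^\\s*(\\S+).*$", "\\1", x)
    grepl("^[0-9]+$", tok)
  }
  skip <- logical(n)
  for (i in seq_len(min(3L, n))) {
    if (is_blank[i] || !first_tok_numeric(lines[i])) skip[i] <- TRUE else break
  }
  keep <- which(!skip & !is_blank)
  if (length(keep) == 0L) return(empty_hits())

  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(toks)

  bad <- which(nf < 14L | nf > 16L)
  if (length(bad))
    stop_data(sprintf("malformed RepeatMasker row at line %d: expected 15 columns (+ optional '*'), found %d",
                      keep[bad[1]], nf[bad[1]]))
  no_id <- which(nf == 14L)
  if (length(no_id))
    stop_data(sprintf(paste0("row at line %d lacks the ID column; ",
                             "rerun RepeatMasker with a version that reports element IDs ",
                             "(fragments of interrupted elements must share an ID)"),
                      keep[no_id[1]]))

  m <- matrix("", nrow = length(toks), ncol = 16L)
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) == 15L) tk <- c(tk, "")
    m[i, ] <- tk
  }

  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(gsub("[()]", "", m[, col])))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop_data(sprintf("malformed RepeatMasker row at line %d: non-numeric %s field '%s'",
                        keep[j], what, m[j, col]))
    }
    v
  }

  strand <- m[, 9]
  ok_strand <- strand %in% c("+", "C", "c")
  if (!all(ok_strand)) {
    j <- which(!ok_strand)[1]
    stop_data(sprintf("malformed RepeatMasker row at line %d: strand field '%s' (expected '+' or 'C')",
                      keep[j], strand[j]))
  }
  strand[strand == "c"] <- "C"

  c12 <- num(12, "consensus"); c13 <- num(13, "consensus"); c14 <- num(14, "consensus")
  plus <- strand == "+"
  # plus rows print: begin end (left); complement rows print: (left) end begin
  cons_begin <- ifelse(plus, c12, c14)
  cons_end   <- c13
  cons_left  <- ifelse(plus, c14, c12)

  hits <- data.frame(
    sw_score     = as.integer(num(1, "score")),
    pct_div      = num(2, "divergence"),
    pct_del      = num(3, "deletion"),
    pct_ins      = num(4, "insertion"),
    query_id     = m[, 5],
    query_begin  = as.integer(num(6, "query coordinate")),
    query_end    = as.integer(num(7, "query coordinate")),
    query_left   = as.integer(num(8, "query remainder")),
    strand       = strand,
    repeat_name  = m[, 10],
    repeat_class = m[, 11],
    cons_begin   = as.integer(cons_begin),
    cons_end     = as.integer(cons_end),
    cons_left    = as.integer(cons_left),
    element_id   = as.integer(num(15, "element ID")),
    overlap_flag = m[, 16] == "*",
    stringsAsFactors = FALSE
  )

  bad_coord <- which(hits$query_begin > hits$query_end | hits$cons_begin > hits$cons_end |
                       hits$query_begin < 1L | hits$cons_begin < 1L)
  if (length(bad_coord))
    stop_data(sprintf("malformed RepeatMasker row at line %d: inverted or non-positive coordinates",
                      keep[bad_coord[1]]))
  if (any(hits$element_id < 1L))
    stop_data("element IDs must be >= 1")
  hits
}

empty_hits <- function() {
  data.frame(
    sw_score = integer(), pct_div = numeric(), pct_del = numeric(),
    pct_ins = numeric(), query_id = character(), query_begin = integer(),
    query_end = integer(), query_left = integer(), strand = character(),
    repeat_name = character(), repeat_class = character(),
    cons_begin = integer(), cons_end = integer(), cons_left = integer(),
    element_id = integer(), overlap_flag = logical(),
    stringsAsFactors = FALSE
  )
}

rm_out_header <- function() {
  c("   SW   perc perc perc  query     position in query              matching  repeat         position in repeat",
    "score   div. del. ins.  sequence  begin  end          (left)     repeat    class/family   begin  end  (left)  ID",
    "")
}

#' Write hits in RepeatMasker .out format
#'
#' Inverse of [read_rm_out()]: emits the standard 15-column layout (plus the
#' optional \code{*} flag) with a three-line header. Consensus coordinates of
#' complement-strand rows are printed in RepeatMasker's reversed dialect,
#' \code{(left) end begin}, so the output is accepted by any .out consumer.
#'
#' @param hits Data frame as returned by [read_rm_out()] or
#'   [simulate_tints()].
#' @param file Output path or connection.
#' @return Invisibly, `file`.
#' @export
write_rm_out <- function(hits, file) {
  stopifnot(is.data.frame(hits))
  plus <- hits$strand == "+"
  f12 <- ifelse(plus, format(hits$cons_begin), sprintf("(%d)", hits$cons_left))
  f13 <- format(hits$cons_end)
  f14 <- ifelse(plus, sprintf("(%d)", hits$cons_left), format(hits$cons_begin))
  rows <- sprintf("%5d %6.1f %4.1f %4.1f  %-12s %8d %8d (%d) %s %-14s %-16s %6s %6s %8s %6d%s",
                  hits$sw_score, hits$pct_div, hits$pct_del, hits$pct_ins,
                  hits$query_id, hits$query_begin, hits$query_end, hits$query_left,
                  hits$strand, hits$repeat_name, hits$repeat_class,
                  f12, f13, f14, hits$element_id,
                  ifelse(hits$overlap_flag, " *", ""))
  writeLines(c(rm_out_header(), rows), file)
  invisible(file)
}

#' Group annotation rows into element instances
#'
#' Rows sharing a \code{(query_id, element_id)} pair are fragments of one
#' genomic element that was interrupted by later insertions. Interrupted
#' elements are occasionally annotated with different subfamily names on
#' their two sides; the instance adopts the name of the largest fragment
#' (by query span), ties broken by the first fragment in query order.
#'
#' @param hits Data frame from [read_rm_out()].
#' @return A data frame with one row per element instance: \code{query_id},
#'   \code{element_id}, \code{type} (resolved subtype name), \code{class},
#'   \code{strand} (of the largest fragment), \code{n_fragments},
#'   \code{query_begin}/\code{query_end} (extent over all fragments),
#'   \code{min_fragment_span} (smallest fragment query span), and
#'   \code{fragments}, a list column of row indices into \code{hits} sorted
#'   by query position.
#' @export
group_elements <- function(hits) {
  if (nrow(hits) == 0L) {
    out <- data.frame(query_id = character(), element_id = integer(),
                      type = character(), class = character(), strand = character(),
                      n_fragments = integer(), query_begin = integer(),
                      query_end = integer(), min_fragment_span = integer(),
                      stringsAsFactors = FALSE)
    out$fragments <- list()
    return(out)
  }
  key <- paste(hits$query_id, hits$element_id, sep = "\r")
  idx <- split(seq_len(nrow(hits)), key)
  # keep instance order by first appearance in the file
  first <- vapply(idx, min, integer(1))
  idx <- idx[order(first)]

  span <- hits$query_end - hits$query_begin + 1L
  rows <- lapply(idx, function(i) i[order(hits$query_begin[i])])
  largest <- vapply(rows, function(i) i[which.max(span[i])], integer(1))

  out <- data.frame(
    query_id   = hits$query_id[vapply(rows, `[`, integer(1), 1L)],
    element_id = hits$element_id[vapply(rows, `[`, integer(1), 1L)],
    type       = hits$repeat_name[largest],
    class      = hits$repeat_class[largest],
    strand     = hits$strand[largest],
    n_fragments = lengths(rows),
    query_begin = vapply(rows, function(i) min(hits$query_begin[i]), integer(1)),
    query_end   = vapply(rows, function(i) max(hits$query_end[i]), integer(1)),
    min_fragment_span = vapply(rows, function(i) min(span[i]), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out$fragments <- unname(rows)
  out
}

# condition helpers: CLI maps these classes onto exit codes
stop_config <- function(msg) stop(errorCondition(msg, class = c("tint_config_error", "error")))
stop_data   <- function(msg) stop(errorCondition(msg, class = c("tint_data_error", "error")))
stop_numeric <- function(msg) stop(errorCondition(msg, class = c("tint_numeric_error", "error")))
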