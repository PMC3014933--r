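#' Build the directional insertion-count matrix
#'
#' Tallies accepted nesting events into a K x K matrix of directional counts:
#' rows are inserted subtypes, columns are host subtypes (the orientation used
#' throughout the package and stated in every serialization header). The
#' per-type genomic copy number is the number of distinct element instances
#' of that subtype among all detected elements, fragments merged by ID.
#'
#' Nested integrations of identical subtypes (self-insertions) are excluded
#' from the tally by default; they can be retained with
#' \code{include_self = TRUE} for model-calibration studies.
#'
#' @param events Event data frame from [detect_tints()].
#' @param instances Instance data frame from [group_elements()]; provides
#'   copy numbers.
#' @param include_self Tally events with identical inserted and host subtype
#'   onto the diagonal.
#' @param types Optional character vector fixing the type set and order;
#'   defaults to all types appearing in \code{events}, ordered by first
#'   appearance in \code{instances}.
#' @return An object of class \code{"tint_matrix"}: a list with elements
#'   \code{types}, \code{counts} (K x K integer matrix, rows = inserted,
#'   cols = host), \code{copy_number} (named integer vector) and
#'   \code{include_self}.
#' @export
build_tint_matrix <- function(events, instances, include_self = FALSE,
                              types = NULL) {
  ev <- events
  if (!include_self && nrow(ev)) ev <- ev[!ev$self_insertion, , drop = FALSE]
  if (is.null(types)) {
    used <- unique(c(ev$inserted_type, ev$host_type))
    types <- unique(instances$type)
    types <- types[types %in% used]
    extra <- setdiff(used, types)
    if (length(extra))
      stop_data(sprintf("event references subtype(s) absent from instances: %s",
                        paste(extra, collapse = ", ")))
  } else {
    extra <- setdiff(unique(c(ev$inserted_type, ev$host_type)), types)
    if (length(extra) && nrow(ev))
      ev <- ev[ev$inserted_type %in% types & ev$host_type %in% types, , drop = FALSE]
  }
  K <- length(types)
  counts <- matrix(0L, K, K, dimnames = list(inserted = types, host = types))
  if (nrow(ev)) {
    tab <- table(factor(ev$inserted_type, types), factor(ev$host_type, types))
    counts <- counts + as.integer(tab)
    dim(counts) <- c(K, K)
    dimnames(counts) <- list(inserted = types, host = types)
  }
  cn <- table(factor(instances$type, types))
  copy_number <- as.integer(cn)
  names(copy_number) <- types
  new_tint_matrix(types, counts, copy_number, include_self)
}

new_tint_matrix <- function(types, counts, copy_number, include_self) {
  structure(list(types = types, counts = counts, copy_number = copy_number,
                 include_self = isTRUE(include_self)),
            class = "tint_matrix")
}

#' @export
print.tint_matrix <- function(x, ...) {
  cat(sprintf("TinT matrix: %d subtypes, %d nested insertions (rows = inserted, cols = host)\n",
              length(x$types), sum(x$counts)))
  m <- cbind(x$counts, inserted_total = rowSums(x$counts),
             copy_number = x$copy_number)
  print(rbind(m, host_total = c(colSums(x$counts), sum(x$counts), sum(x$copy_number))))
  invisible(x)
}

#' Row and column totals of a TinT matrix
#'
#' @param m A \code{tint_matrix}.
#' @return A list with \code{inserted_total} (row sums) and
#'   \code{host_total} (column sums).
#' @export
tint_margins <- function(m) {
  list(inserted_total = rowSums(m$counts), host_total = colSums(m$counts))
}

#' Merge related subtypes in a TinT matrix
#'
#' Sums the rows, columns and copy numbers of the member subtypes of each
#' group into one merged subtype, e.g. combining closely related subfamilies
#' whose individual resolution is too low. Counts between members of one
#' group land on the merged diagonal, where the usual self-insertion policy
#' of the downstream likelihood applies.
#'
#' @param m A \code{tint_matrix}.
#' @param groups Named list: \code{list(AluYR = c("AluYRb","AluYRc","AluYRd"))}.
#'   Groups must be disjoint and members must exist in \code{m$types}.
#' @return A merged \code{tint_matrix}; total counts and total copy number
#'   are conserved.
#' @export
merge_types <- function(m, groups) {
  stopifnot(inherits(m, "tint_matrix"))
  if (length(groups) == 0L) return(m)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop_config("merge groups must be a named list")
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members))
    stop_config("merge groups overlap: each subtype may belong to one group only")
  unknown <- setdiff(members, m$types)
  if (length(unknown))
    stop_config(sprintf("unknown subtype(s) in merge groups: %s",
                        paste(unknown, collapse = ", ")))

  map <- stats::setNames(m$types, m$types)
  for (g in names(groups)) map[groups[[g]]] <- g
  new_types <- unique(unname(map))
  f <- factor(unname(map), levels = new_types)

  counts <- rowsum(m$counts, f, reorder = FALSE)
  counts <- t(rowsum(t(counts), f, reorder = FALSE))
  counts <- matrix(as.integer(counts), length(new_types), length(new_types),
                   dimnames = list(inserted = new_types, host = new_types))
  cn <- as.integer(rowsum(as.numeric(m$copy_number), f, reorder = FALSE))
  names(cn) <- new_types
  new_tint_matrix(new_types, counts, cn, m$include_self)
}

#' Drop weakly connected subtypes
#'
#' The activity model requires each subtype to interact with at least two
#' other subtypes (as host or as inserted element, off-diagonal). Subtypes
#' below \code{min_partner_types} distinct partners or below
#' \code{min_total_events} off-diagonal events are removed; removal is
#' iterated to a fixed point because dropping one subtype can strand
#' another's last partner.
#'
#' @param m A \code{tint_matrix}.
#' @param min_partner_types Minimal number of distinct interaction partners.
#' @param min_total_events Minimal number of off-diagonal events a subtype
#'   participates in.
#' @return A filtered \code{tint_matrix}; removed types are recorded in the
#'   \code{"removed"} attribute.
#' @export
filter_types <- function(m, min_partner_types = 2, min_total_events = 1) {
  stopifnot(inherits(m, "tint_matrix"))
  removed <- character()
  repeat {
    K <- length(m$types)
    if (K == 0L)
      stop_data(paste("all subtypes removed by interaction filtering;",
                      "consider relaxed detection conditions (recommended only",
                      "when the amount of data is reduced)"))
    off <- m$counts
    if (K) diag(off) <- 0L
    partners <- vapply(seq_len(K), function(j)
      sum((off[j, ] + off[, j]) > 0L), integer(1))
    events <- rowSums(off) + colSums(off)
    drop <- partners < min_partner_types | events < min_total_events
    if (!any(drop)) break
    removed <- c(removed, m$types[drop])
    keep <- !drop
    m <- new_tint_matrix(m$types[keep],
                         m$counts[keep, keep, drop = FALSE],
                         m$copy_number[keep], m$include_self)
  }
  if (length(m$types) == 0L)
    stop_data(paste("all subtypes removed by interaction filtering;",
                    "consider relaxed detection conditions (recommended only",
                    "when the amount of data is reduced)"))
  attr(m, "removed") <- removed
  m
}

#' Serialize a TinT matrix
#'
#' Tab-separated table with leading comment lines stating the orientation
#' (\code{# rows=inserted cols=host}); the last column is the per-type copy
#' number.
#'
#' @param m A \code{tint_matrix}.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @seealso [read_tint_matrix()]
#' @export
write_tint_matrix <- function(m, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c("# TinT directional insertion-count matrix",
               "# rows=inserted cols=host; last column = genomic copy number"), con)
  tab <- data.frame(type = m$types, m$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  tab$copy_number <- m$copy_number
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a serialized TinT matrix
#'
#' @param file Path written by [write_tint_matrix()].
#' @return A \code{tint_matrix}.
#' @export
read_tint_matrix <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = TRUE, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  types <- tab$type
  cn <- as.integer(tab$copy_number)
  names(cn) <- types
  counts <- as.matrix(tab[, types, drop = FALSE])
  counts <- matrix(as.integer(counts), length(types), length(types),
                   dimnames = list(inserted = types, host = types))
  new_tint_matrix(types, counts, cn, include_self = any(diag(counts) > 0L))
}

#' Read an element-grouping file
#'
#' Plain-text grouping of subtypes for [merge_types()]: one group per line in
#' the form \code{new_name = member1, member2, ...}. Blank lines and lines
#' starting with \code{#} are ignored.
#'
#' @param file Path to the grouping file.
#' @return Named list of member character vectors.
#' @export
read_groups <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  groups <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop_config(sprintf("malformed grouping line (expected 'name = a, b, ...'): %s", ln))
    members <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    members <- members[nzchar(members)]
    if (!length(members))
      stop_config(sprintf("grouping line has no members: %s", ln))
    groups[[trimws(parts[1])]] <- members
  }
  groups
}

#' Render a matrix table with margins
#'
#' Writes the count matrix in the display layout: copy-number column on the
#' right, inserted-element sums to the right of it, and host sums across the
#' bottom.
#'
#' @param m A \code{tint_matrix}.
#' @param file Optional output path; when \code{NULL} the character matrix is
#'   returned.
#' @return Invisibly `file`, or the character matrix when \code{file} is
#'   \code{NULL}.
#' @export
render_matrix_table <- function(m, file = NULL) {
  marg <- tint_margins(m)
  body <- cbind(m$counts, inserted_total = marg$inserted_total,
                copy_number = m$copy_number)
  tab <- rbind(body, host_total = c(marg$host_total, sum(m$counts),
                                    sum(m$copy_number)))
  out <- cbind(type = rownames(tab), apply(tab, 2, as.character))
  rownames(out) <- NULL
  if (is.null(file)) return(out)
  con <- file(file, "w"); on.exit(close(con))
  writeLines("# rows=inserted cols=host; margins: inserted_total right, host_total bottom", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
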