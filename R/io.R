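# File formats: FASTA and relaxed PHYLIP alignments, Newick trees, the
# plain-text rate-matrix format, and JSON run configs.  User-facing matrices
# default to alphabetical A,C,G,T base order; the hierarchy's native AGCT and PAML's
# TCAG orders are available everywhere via `base_order`.

.lmm_reorder_matrix <- function(Q, from = "canonical", to = "alpha") {
  b_from <- lmm_base_order(from); b_to <- lmm_base_order(to)
  perm <- match(b_to, b_from)
  out <- Q[perm, perm, drop = FALSE]
  dimnames(out) <- list(b_to, b_to)
  out
}

#' Convert a rate matrix between base orders and sum conventions
#'
#' @param Q 4x4 matrix with dimnames giving its current base order.
#' @param base_order `"alpha"` (A,C,G,T), `"canonical"` (A,G,C,T) or
#'   `"paml"` (T,C,A,G).
#' @param transpose if TRUE, returns the rows-sum-to-zero transpose for
#'   consumers using the opposite convention.
#' @export
format_rate_matrix <- function(Q, base_order = "alpha", transpose = FALSE) {
  cur <- rownames(Q)
  if (is.null(cur)) cur <- lmm_base_order("canonical")
  from <- if (identical(cur, lmm_base_order("alpha"))) "alpha"
          else if (identical(cur, lmm_base_order("paml"))) "paml"
          else "canonical"
  out <- .lmm_reorder_matrix(Q, from, base_order)
  if (transpose) t(out) else out
}

#' Write / read a rate matrix as plain text
#'
#' Header line records the base order and sum convention; numbers are written
#' with full precision so the round-trip is bit-exact.
#'
#' @param Q 4x4 rate matrix.
#' @param path file path.
#' @param base_order see [format_rate_matrix()].
#' @param transpose write the rows-sum-to-zero transpose.
#' @export
write_rate_matrix <- function(Q, path, base_order = "alpha",
                              transpose = FALSE) {
  M <- format_rate_matrix(Q, base_order, transpose)
  hdr <- sprintf("# base_order=%s convention=%s",
                 paste(rownames(M), collapse = ""),
                 if (transpose) "rows_sum_zero" else "columns_sum_zero")
  lines <- c(hdr, vapply(seq_len(4), function(i)
    paste(sprintf("%.17g", M[i, ]), collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rate_matrix
#' @return `read_rate_matrix` returns the matrix in canonical A,G,C,T order,
#'   columns summing to zero, whatever the file's declared order/convention.
#' @export
read_rate_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  ord <- sub(".*base_order=([ACGT]{4}).*", "\\1", hdr)
  conv <- sub(".*convention=([a-z_]+).*", "\\1", hdr)
  M <- do.call(rbind, lapply(lines[2:5], function(l)
    as.numeric(strsplit(l, "\t")[[1]])))
  bases <- strsplit(ord, "")[[1]]
  dimnames(M) <- list(bases, bases)
  if (conv == "rows_sum_zero") M <- t(M)
  from <- if (identical(bases, lmm_base_order("alpha"))) "alpha"
          else if (identical(bases, lmm_base_order("paml"))) "paml"
          else "canonical"
  .lmm_reorder_matrix(M, from, "canonical")
}

#' Read an alignment from FASTA or relaxed PHYLIP
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"` (relaxed sequential: header line
#'   `ntaxa nsites`, then whitespace-separated name + sequence per taxon,
#'   sequences possibly wrapped).
#' @return an [lmm_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "fasta") {
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop("not a FASTA file (no '>' headers): ", path)
    ends <- c(hdr[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      block <- lines[(hdr[i] + 1L):ends[i]]
      paste(gsub("\\s", "", block), collapse = "")
    }, character(1))
    names(seqs) <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr])
    return(lmm_alignment(seqs))
  }
  # relaxed phylip
  lines <- lines[nzchar(trimws(lines))]
  head_nums <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(head_nums) != 2 || anyNA(head_nums)) {
    stop("bad PHYLIP header: ", lines[1])
  }
  ntax <- head_nums[1]; nsit <- head_nums[2]
  body <- lines[-1]
  seqs <- character(0)
  for (l in body) {
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(seqs) < ntax &&
        (length(seqs) == 0 || nchar(seqs[length(seqs)]) >= nsit)) {
      seqs[parts[1]] <- paste(parts[-1], collapse = "")
    } else {
      seqs[length(seqs)] <- paste0(seqs[length(seqs)],
                                   paste(parts, collapse = ""))
    }
  }
  if (length(seqs) != ntax) {
    stop("PHYLIP header promises ", ntax, " taxa but file has ", length(seqs))
  }
  if (any(nchar(seqs) != nsit)) {
    stop("PHYLIP header promises ", nsit, " sites but sequences have ",
         paste(unique(nchar(seqs)), collapse = ", "))
  }
  lmm_alignment(seqs)
}

#' Write an alignment as FASTA
#'
#' @param alignment an [lmm_alignment()].
#' @param path file path.
#' @param width line-wrap width (0 = single line, used for bit-exact
#'   round-trips).
#' @export
write_alignment <- function(alignment, path, width = 60) {
  bases <- lmm_base_order("canonical")
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(alignment$taxa)) {
    s <- ifelse(is.na(alignment$states[i, ]), "-",
                bases[alignment$states[i, ]])
    s <- paste(s, collapse = "")
    writeLines(paste0(">", alignment$taxa[i]), con)
    if (width > 0) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
    } else writeLines(s, con)
  }
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over ape with the rooted/unrooted distinction made explicit.
#'
#' @param path file path.
#' @param rooted require a rooted tree (error, with a pointer to
#'   [midpoint_root()], if the file contains an unrooted one).
#' @export
read_tree <- function(path, rooted = FALSE) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (rooted && !ape::is.rooted(tr)) {
    stop("tree in ", path, " is unrooted (root degree > 2); ",
         "root it first, e.g. with midpoint_root()")
  }
  tr
}

#' @rdname read_tree
#' @param tree `phylo` object.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read a JSON run configuration
#'
#' @param path JSON file with fields such as `command`, `input`, `models`,
#'   `heterogeneities`, `seed`, `out`.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
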