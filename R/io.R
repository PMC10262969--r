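#' Read a multiple sequence alignment
#'
#' Supports FASTA (wrapped or unwrapped) and relaxed sequential PHYLIP (header
#' line `ntaxa nsites`, then one `name sequence` line per taxon; long names
#' and spaces inside the sequence are accepted). Input is upper-cased and
#' validated: ragged rows name the offending taxon, unknown symbols report
#' the 1-based site index.
#'
#' @param path input file
#' @param format "fasta" or "phylip"
#' @return an [Alignment-class]
#' @export
readAlignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "fasta") {
    hd <- grep("^>", lines)
    if (!length(hd)) stop("no FASTA headers found")
    nm <- sub("^>\\s*", "", lines[hd])
    nm <- sub("\\s.*$", "", nm)
    starts <- hd + 1
    ends <- c(hd[-1] - 1, length(lines))
    seqs <- vapply(seq_along(hd), function(i) {
      paste(gsub("\\s", "", lines[seq(starts[i], max(starts[i], ends[i]))]),
            collapse = "")
    }, "")
    if (hd[1] == length(lines) || any(ends < starts))
      seqs[ends < starts] <- ""
    alignment(setNames(seqs, nm))
  } else {
    lines <- lines[nzchar(trimws(lines))]
    hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(hdr) < 2) stop("malformed PHYLIP header")
    n <- as.integer(hdr[1]); L <- as.integer(hdr[2])
    body <- lines[-1]
    if (length(body) < n)
      stop(sprintf("expected %d sequences, found %d lines", n, length(body)))
    nm <- character(n); sq <- character(n)
    for (i in seq_len(n)) {
      tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
      nm[i] <- tok[1]
      sq[i] <- paste(tok[-1], collapse = "")
    }
    # wrapped sequential blocks: append continuation lines round-robin
    extra <- body[-seq_len(n)]
    if (length(extra)) {
      for (j in seq_along(extra)) {
        i <- (j - 1) %% n + 1
        sq[i] <- paste0(sq[i], gsub("\\s", "", extra[j]))
      }
    }
    if (any(nchar(sq) != L))
      stop(sprintf("taxon '%s' has %d sites, header says %d",
                   nm[which(nchar(sq) != L)[1]],
                   nchar(sq)[which(nchar(sq) != L)[1]], L))
    alignment(setNames(sq, nm))
  }
}

#' Write an alignment
#'
#' FASTA wraps sequences at 80 columns; relaxed PHYLIP writes one
#' `name sequence` line per taxon after the `ntaxa nsites` header.
#'
#' @param aln an [Alignment-class]
#' @param path output file
#' @param format "fasta" or "phylip"
#' @return the path, invisibly
#' @export
writeAlignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  m <- alnMatrix(aln)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    for (i in seq_len(nrow(m))) {
      writeLines(paste0(">", rownames(m)[i]), con)
      s <- paste(m[i, ], collapse = "")
      writeLines(substring(s, seq(1, nchar(s), 80),
                           pmin(seq(1, nchar(s), 80) + 79, nchar(s))), con)
    }
  } else {
    writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(rownames(m)[i], paste(m[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Write a synthetic (or real) locus set to disk
#'
#' Emits one FASTA per locus, a manifest TSV (locus id, class, taxa, length,
#' missing-data proportion, divergence) and, when truth trees are attached,
#' one Newick per locus.
#'
#' @param loci list of [Locus-class]
#' @param dir output directory (created if needed)
#' @return the manifest data.frame, invisibly
#' @export
writeLocusSet <- function(loci, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- do.call(rbind, lapply(loci, function(lc) {
    m <- alnMatrix(locusAlignment(lc))
    writeAlignment(locusAlignment(lc),
                   file.path(dir, paste0(locusId(lc), ".fasta")))
    tr <- locusTree(lc)
    if (!is.null(tr))
      ape::write.tree(tr, file.path(dir, paste0(locusId(lc), ".nwk")))
    data.frame(id = locusId(lc), class = lc@datasetClass, taxa = nrow(m),
               length = ncol(m),
               missp = mean(m %in% c("-", "?", "N")),
               divergence = locusDivergence(lc), stringsAsFactors = FALSE)
  }))
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(man)
}
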