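#' Multiple sequence alignment container
#'
#' An `Alignment` holds an equal-length, taxon-labelled nucleotide matrix over
#' the IUPAC alphabet plus gap (`-`) and unknown (`?`) symbols, stored
#' upper-case, one row per taxon. It is the universal sequence container of
#' the package: simulators emit it, the likelihood/parsimony engines and all
#' compositional diagnostics consume it.
#'
#' @slot seqs character matrix, rows named by taxon, entries single characters
#'   from the allowed alphabet.
#'
#' @seealso [alignment()], [readAlignment()], [simulateAlignment()]
#' @export
setClass("Alignment", representation(seqs = "matrix"))

setValidity("Alignment", function(object) {
  m <- object@seqs
  if (!is.character(m)) return("seqs must be a character matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("taxon labels must be present and unique")
  bad <- matrix(!(m %in% ALPHABET), nrow(m))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    return(sprintf("disallowed symbol '%s' for taxon '%s' at site %d",
                   m[bad][1], rownames(m)[idx[1]], idx[2]))
  }
  TRUE
})

#' Construct an Alignment from a character matrix or vector of strings
#'
#' @param x either a character matrix (rows = taxa) of single characters, or a
#'   named character vector of equal-length sequence strings.
#' @return an [Alignment-class] object; input is upper-cased.
#' @examples
#' alignment(c(tax1 = "ACGT", tax2 = "ac-t"))
#' @export
alignment <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    if (is.null(names(x))) stop("sequences must be named by taxon")
    n <- nchar(x)
    if (length(unique(n)) > 1) {
      off <- names(x)[which(n != n[1])[1]]
      stop(sprintf("ragged alignment: taxon '%s' has %d sites, expected %d",
                   off, nchar(x[off]), n[1]))
    }
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  }
  obj <- new("Alignment", seqs = m)
  validObject(obj)
  obj
}

#' @describeIn alignment number of taxa
#' @param aln an Alignment
#' @export
nTaxa <- function(aln) nrow(aln@seqs)

#' @describeIn alignment number of sites (columns)
#' @export
nSites <- function(aln) ncol(aln@seqs)

#' @describeIn alignment taxon labels
#' @export
alnTaxa <- function(aln) rownames(aln@seqs)

#' @describeIn alignment the raw character matrix
#' @export
alnMatrix <- function(aln) aln@seqs

#' Subset an alignment by taxa and/or sites
#' @param x an Alignment
#' @param i taxon selector (names or indices)
#' @param j site selector
#' @param ... ignored
#' @param drop ignored (never drops)
#' @export
setMethod("[", "Alignment", function(x, i, j, ..., drop = FALSE) {
  m <- x@seqs
  if (!missing(i)) m <- m[i, , drop = FALSE]
  if (!missing(j)) m <- m[, j, drop = FALSE]
  new("Alignment", seqs = m)
})

setMethod("show", "Alignment", function(object) {
  cat(sprintf("Alignment: %d taxa x %d sites\n", nTaxa(object), nSites(object)))
  lab <- alnTaxa(object)
  k <- min(5L, length(lab))
  for (t in seq_len(k)) {
    s <- paste(object@seqs[t, seq_len(min(50L, nSites(object)))], collapse = "")
    cat(sprintf("  %-15s %s%s\n", lab[t], s,
                if (nSites(object) > 50) "..." else ""))
  }
  if (length(lab) > k) cat(sprintf("  ... and %d more taxa\n", length(lab) - k))
})

#' GTR+Gamma substitution model
#'
#' A reversible nucleotide substitution model with equilibrium frequencies
#' `pi`, six exchangeabilities (order AC, AG, AT, CG, CT, GT), discrete-gamma
#' rate variation with shape `alpha` and `ncat` equal-probability categories
#' (category rate = the conditional mean of its gamma slice, renormalized to
#' average exactly 1), and an optional proportion of invariant sites `pInv`.
#' The rate matrix is normalized so the expected substitution rate at
#' equilibrium, averaged over rate classes, equals 1. The same class also
#' carries the 2-state purine/pyrimidine reduction used for RY-coded data
#' (see [ryModel()]); `states` records the state space.
#'
#' @slot states character vector of state labels ("A","C","G","T" or "R","Y")
#' @slot pi equilibrium state frequencies
#' @slot exch exchangeabilities (length 6 for nucleotides, 1 for RY)
#' @slot alpha gamma shape
#' @slot ncat number of discrete gamma categories
#' @slot pInv proportion of invariant sites
#' @slot Q normalized rate matrix
#' @slot catRates per-category relative rates (including the 1/(1-pInv)
#'   rescaling when pInv > 0; the invariant class itself has rate 0 and is
#'   appended at likelihood time)
#' @slot eigenVals,eigenVecs,eigenInv spectral decomposition of Q
#'
#' @seealso [buildModel()], [transitionMatrix()], [gammaCategoryRates()]
#' @export
setClass("GTRGamma", representation(
  states = "character", pi = "numeric", exch = "numeric", alpha = "numeric",
  ncat = "integer", pInv = "numeric", Q = "matrix", catRates = "numeric",
  eigenVals = "numeric", eigenVecs = "matrix", eigenInv = "matrix"
))

setValidity("GTRGamma", function(object) {
  ns <- length(object@states)
  if (length(object@pi) != ns) return("pi length must match states")
  if (abs(sum(object@pi) - 1) > 1e-9) return("pi must sum to 1")
  if (any(object@pi < 0)) return("pi must be non-negative")
  if (any(object@exch <= 0)) return("exchangeabilities must be positive")
  if (object@alpha <= 0) return("alpha must be positive")
  if (object@pInv < 0 || object@pInv >= 1) return("pInv must be in [0, 1)")
  if (any(abs(rowSums(object@Q)) > 1e-8)) return("Q rows must sum to 0")
  TRUE
})

setMethod("show", "GTRGamma", function(object) {
  cat(sprintf("%s model (%d states)\n",
              if (length(object@states) == 4) "GTR+Gamma" else "2-state reversible",
              length(object@states)))
  cat("  pi:   ", paste(sprintf("%s=%.4f", object@states, object@pi),
                        collapse = " "), "\n")
  cat("  exch: ", paste(sprintf("%.4g", object@exch), collapse = " "), "\n")
  cat(sprintf("  alpha = %.4g, ncat = %d, pInv = %.3g\n",
              object@alpha, object@ncat, object@pInv))
})

#' A locus: alignment plus per-locus metadata
#'
#' Carries one locus through the pipeline: its alignment, dataset class label
#' (CNEE / intron / UCE / C123 / C12 / C3 / synthetic), the per-locus tree with
#' branch lengths fitted on the fixed topology, the divergence-from-ancestor
#' summary used for stratification, and exclusion flags (long-branch,
#' relative-branch, recombination, selection) with their provenance.
#'
#' @slot id locus identifier
#' @slot aln the [Alignment-class]
#' @slot datasetClass dataset class label
#' @slot tree per-locus `phylo` tree or NULL (stored in a list slot)
#' @slot divergence mean branch length from the ingroup common ancestor
#'   (substitutions/site; NA until computed)
#' @slot flags named logical vector of exclusion flags
#' @export
setClass("Locus", representation(
  id = "character", aln = "Alignment", datasetClass = "character", tree = "list",
  divergence = "numeric", flags = "logical"
))

#' Construct a Locus
#' @param id locus identifier
#' @param aln an [Alignment-class]
#' @param class dataset class label
#' @param tree optional `phylo` with per-locus branch lengths
#' @param divergence optional precomputed divergence summary value
#' @param flags named logical exclusion flags (e.g. recombination, selection)
#' @return a [Locus-class]
#' @export
locus <- function(id, aln, class = "synthetic", tree = NULL,
                  divergence = NA_real_, flags = c(recombination = FALSE,
                                                   selection = FALSE)) {
  new("Locus", id = as.character(id), aln = aln, datasetClass = class,
      tree = if (is.null(tree)) list() else list(tree),
      divergence = divergence, flags = flags)
}

#' @describeIn locus locus identifier
#' @param x a Locus
#' @export
locusId <- function(x) x@id

#' @describeIn locus the per-locus tree (or NULL)
#' @export
locusTree <- function(x) if (length(x@tree)) x@tree[[1]] else NULL

#' @describeIn locus the alignment
#' @export
locusAlignment <- function(x) x@aln

#' @describeIn locus divergence-from-ancestor value
#' @export
locusDivergence <- function(x) x@divergence

setMethod("show", "Locus", function(object) {
  cat(sprintf("Locus '%s' [%s]: %d taxa x %d sites%s\n", object@id,
              object@datasetClass, nTaxa(object@aln), nSites(object@aln),
              if (any(object@flags)) paste0(" flags: ",
                paste(names(object@flags)[object@flags], collapse = ","))
              else ""))
})
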