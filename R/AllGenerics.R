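#' Accessors for dockiface S4 objects
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{atoms()} returns the atom table of a complex (optionally one
#' chain's), \code{receptorChain()}/\code{ligandChain()} the chain ids,
#' \code{complexLabel()} the identifier, \code{totalArea()},
#' \code{atomArea()} and \code{residueArea()} the pieces of a
#' [SasaResult-class], \code{contactPairs()} and \code{contactCutoff()} the
#' content of a [ContactMap-class], \code{decoyFnat()}/\code{decoyIrmsd()}
#' the quality metrics, and \code{featureMatrix()}/\code{setLabels()}/
#' \code{setMeta()} the content of a [LabeledSet-class].
#'
#' @param x the object.
#' @param chain for \code{atoms()}: "receptor", "ligand" or "both".
#' @return the corresponding slot content (see each class's documentation).
#' @name accessors
#' @aliases atoms receptorChain ligandChain complexLabel totalArea atomArea
#'   residueArea contactPairs contactCutoff decoyFnat decoyIrmsd
#'   featureMatrix setLabels setMeta
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x, chain = c("both", "receptor", "ligand"))
  standardGeneric("atoms"))

#' @rdname accessors
#' @export
setMethod("atoms", "DimerComplex", function(x, chain = c("both", "receptor", "ligand")) {
  chain <- match.arg(chain)
  switch(chain,
    both = x@atoms,
    receptor = x@atoms[x@atoms$chainId == x@receptorChain, , drop = FALSE],
    ligand = x@atoms[x@atoms$chainId == x@ligandChain, , drop = FALSE])
})

#' @rdname accessors
#' @export
setGeneric("receptorChain", function(x) standardGeneric("receptorChain"))
#' @rdname accessors
#' @export
setMethod("receptorChain", "DimerComplex", function(x) x@receptorChain)

#' @rdname accessors
#' @export
setGeneric("ligandChain", function(x) standardGeneric("ligandChain"))
#' @rdname accessors
#' @export
setMethod("ligandChain", "DimerComplex", function(x) x@ligandChain)

#' @rdname accessors
#' @export
setGeneric("complexLabel", function(x) standardGeneric("complexLabel"))
#' @rdname accessors
#' @export
setMethod("complexLabel", "DimerComplex", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("totalArea", function(x) standardGeneric("totalArea"))
#' @rdname accessors
#' @export
setMethod("totalArea", "SasaResult", function(x) x@total)

#' @rdname accessors
#' @export
setGeneric("atomArea", function(x) standardGeneric("atomArea"))
#' @rdname accessors
#' @export
setMethod("atomArea", "SasaResult", function(x) x@atomArea)

#' @rdname accessors
#' @export
setGeneric("residueArea", function(x) standardGeneric("residueArea"))
#' @rdname accessors
#' @export
setMethod("residueArea", "SasaResult", function(x) x@residueArea)

#' @rdname accessors
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))
#' @rdname accessors
#' @export
setMethod("contactPairs", "ContactMap", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("contactCutoff", function(x) standardGeneric("contactCutoff"))
#' @rdname accessors
#' @export
setMethod("contactCutoff", "ContactMap", function(x) x@cutoff)

#' @rdname accessors
#' @export
setGeneric("decoyFnat", function(x) standardGeneric("decoyFnat"))
#' @rdname accessors
#' @export
setMethod("decoyFnat", "DecoyQuality", function(x) x@fnat)

#' @rdname accessors
#' @export
setGeneric("decoyIrmsd", function(x) standardGeneric("decoyIrmsd"))
#' @rdname accessors
#' @export
setMethod("decoyIrmsd", "DecoyQuality", function(x) x@irmsd)

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setMethod("featureMatrix", "LabeledSet", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("setLabels", function(x) standardGeneric("setLabels"))
#' @rdname accessors
#' @export
setMethod("setLabels", "LabeledSet", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("setMeta", function(x) standardGeneric("setMeta"))
#' @rdname accessors
#' @export
setMethod("setMeta", "LabeledSet", function(x) x@meta)
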