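#' Accessors for submatkit classes
#'
#' \code{alphabet} returns the ordered residue codes of a
#' \code{SubstitutionMatrix}; \code{scores} its numeric score table;
#' \code{matrixName} its label; \code{isIntegerValued} whether all entries are
#' whole numbers. \code{corrPairs} returns the 0-based index pairs of a
#' \code{Correspondence}. \code{msaRows} / \code{msaIds} return the gapped rows
#' and ids of an \code{Msa}.
#'
#' @param x,object the object.
#' @param ... unused.
#' @return See the description per accessor.
#' @name accessors
#' @examples
#' m <- unitMatrix(5, 0)
#' alphabet(m)
#' scores(m)[1:3, 1:3]
NULL

#' @rdname accessors
#' @export
setGeneric("alphabet", function(x, ...) standardGeneric("alphabet"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("matrixName", function(x) standardGeneric("matrixName"))

#' @rdname accessors
#' @export
setGeneric("isIntegerValued", function(x) standardGeneric("isIntegerValued"))

#' @rdname accessors
#' @export
setGeneric("corrPairs", function(x) standardGeneric("corrPairs"))

#' @rdname accessors
#' @export
setGeneric("msaRows", function(x) standardGeneric("msaRows"))

#' @rdname accessors
#' @export
setGeneric("msaIds", function(x) standardGeneric("msaIds"))

#' @rdname accessors
setMethod("alphabet", "SubstitutionMatrix", function(x, ...) x@alphabet)

#' @rdname accessors
setMethod("scores", "SubstitutionMatrix", function(x, ...) x@scores)

#' @rdname accessors
setMethod("matrixName", "SubstitutionMatrix", function(x) x@name)

#' @rdname accessors
setMethod("isIntegerValued", "SubstitutionMatrix", function(x) x@integerValued)

#' @rdname accessors
setMethod("corrPairs", "Correspondence", function(x) x@pairs)

#' @rdname accessors
setMethod("msaRows", "Msa", function(x) x@rows)

#' @rdname accessors
setMethod("msaIds", "Msa", function(x) x@ids)

setMethod("show", "SubstitutionMatrix", function(object) {
    cat(sprintf("SubstitutionMatrix '%s': %d residues, %s-valued\n",
                object@name, length(object@alphabet),
                if (object@integerValued) "integer" else "real"))
    cat("  score range:", paste(range(object@scores), collapse = " .. "), "\n")
})

setMethod("show", "WeightedCounts", function(object) {
    cat(sprintf("WeightedCounts: total mass %.4g from %d families\n",
                object@total, object@nFamilies))
})

setMethod("show", "UngappedPairBlock", function(object) {
    cat(sprintf("UngappedPairBlock (family %s), %d columns\n",
                object@familyId, nchar(object@seqA)))
})

setMethod("show", "StructureChain", function(object) {
    cat(sprintf("StructureChain '%s': %d residues (CA trace)\n",
                object@chainId, length(object@residues)))
})

setMethod("show", "Correspondence", function(object) {
    cat(sprintf("Correspondence: %d residue pairs\n", nrow(object@pairs)))
})

setMethod("show", "Msa", function(object) {
    cat(sprintf("Msa: %d sequences x %d columns\n",
                length(object@rows), nchar(object@rows[1])))
})

setMethod("length", "StructureChain", function(x) length(x@residues))
setMethod("length", "Correspondence", function(x) nrow(x@pairs))
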