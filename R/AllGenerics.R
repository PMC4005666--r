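# Generics and accessors. Slots are never touched directly by user code.

#' Atom table of a structure
#'
#' @param x an `RNAStructure`.
#' @return a data.frame with one row per atom: `chain`, `resno`, `insert`,
#'   `resname`, `base` (parent base after RNA mapping, `NA` otherwise),
#'   `elety` (atom name), `x`, `y`, `z` (angstroms), `o` (occupancy).
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "RNAStructure", function(x) x@atoms)

#' Nucleotide table of a structure
#'
#' One row per residue in file order, with a `key` (`chain:resno[insert]`)
#' used throughout the package to reference nucleotides, the mapped `base`
#' (A/C/G/U or `NA` for non-RNA residues) and a `complete` flag: all expected
#' heavy atoms present (the 5' phosphate group is not required of a chain's
#' first residue, and OP3 is never required).
#'
#' @param x an `RNAStructure`.
#' @return data.frame with columns `key`, `chain`, `resno`, `insert`,
#'   `resname`, `base`, `complete`.
#' @export
setGeneric("nucleotides", function(x) standardGeneric("nucleotides"))

#' Eligibility of a structure for motif scanning
#'
#' A model is eligible when it contains at least ten complete nucleotides.
#'
#' @param x an `RNAStructure`.
#' @return logical(1).
#' @export
setGeneric("eligible", function(x) standardGeneric("eligible"))

#' @rdname eligible
#' @export
setMethod("eligible", "RNAStructure", function(x) {
  sum(nucleotides(x)$complete) >= 10L
})

#' Source identifier of a structure
#' @param x an `RNAStructure`.
#' @return character(1) accession or file name.
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname sourceId
#' @export
setMethod("sourceId", "RNAStructure", function(x) x@sourceId)

#' Frame accessors
#'
#' `frameOrigin` returns the origin (midpoint of the first pair's C1' atoms);
#' `frameTriad` the 3x3 right-handed orthonormal matrix whose columns are the
#' helix axis, the projected Watson-Crick hydrogen-bond direction and their
#' normal; `framePairs` the nucleotide keys of the two base pairs.
#'
#' @param x a `HelixFrame`.
#' @return numeric(3), 3x3 matrix, or character(4) respectively.
#' @export
setGeneric("frameOrigin", function(x) standardGeneric("frameOrigin"))

#' @rdname frameOrigin
#' @export
setMethod("frameOrigin", "HelixFrame", function(x) x@origin)

#' @rdname frameOrigin
#' @export
setGeneric("frameTriad", function(x) standardGeneric("frameTriad"))

#' @rdname frameOrigin
#' @export
setMethod("frameTriad", "HelixFrame", function(x) x@triad)

#' @rdname frameOrigin
#' @export
setGeneric("framePairs", function(x) standardGeneric("framePairs"))

#' @rdname frameOrigin
#' @export
setMethod("framePairs", "HelixFrame", function(x) c(x@pair1, x@pair2))

#' Rigid-transform accessors
#' @param x a `RigidTransform`.
#' @return `rotationMatrix`: 3x3 proper rotation; `translationVector`:
#'   numeric(3) in angstroms (reference-frame coordinates).
#' @export
setGeneric("rotationMatrix", function(x) standardGeneric("rotationMatrix"))

#' @rdname rotationMatrix
#' @export
setMethod("rotationMatrix", "RigidTransform", function(x) x@rotation)

#' @rdname rotationMatrix
#' @export
setGeneric("translationVector", function(x) standardGeneric("translationVector"))

#' @rdname rotationMatrix
#' @export
setMethod("translationVector", "RigidTransform", function(x) x@translation)

#' Role map of a k-turn assignment
#' @param x a `KTurnAssignment`.
#' @return named character vector, role label -> nucleotide key.
#' @export
setGeneric("roles", function(x) standardGeneric("roles"))

#' @rdname roles
#' @export
setMethod("roles", "KTurnAssignment", function(x) x@roles)

#' @rdname roles
#' @export
setGeneric("completeCore", function(x) standardGeneric("completeCore"))

#' @rdname roles
#' @export
setMethod("completeCore", "KTurnAssignment", function(x) x@completeCore)

#' Contact-report accessors
#' @param x a `ContactReport`.
#' @return `contacts`: data.frame of measured contacts; `nClass`: "N1",
#'   "N3" or "undetermined".
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' @rdname contacts
#' @export
setMethod("contacts", "ContactReport", function(x) x@contacts)

#' @rdname contacts
#' @export
setGeneric("nClass", function(x) standardGeneric("nClass"))

#' @rdname contacts
#' @export
setMethod("nClass", "ContactReport", function(x) x@nClass)

#' Fitted binding parameters of an ITC fit
#' @param x an `ItcFit`.
#' @return `fitParams`: the `BindingParams`; `fitSE`: named standard errors;
#'   `fitConverged`: logical; `fitFlags`: character vector of diagnostics.
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))

#' @rdname fitParams
#' @export
setMethod("fitParams", "ItcFit", function(x) x@params)

#' @rdname fitParams
#' @export
setGeneric("fitSE", function(x) standardGeneric("fitSE"))

#' @rdname fitParams
#' @export
setMethod("fitSE", "ItcFit", function(x) x@se)

#' @rdname fitParams
#' @export
setGeneric("fitConverged", function(x) standardGeneric("fitConverged"))

#' @rdname fitParams
#' @export
setMethod("fitConverged", "ItcFit", function(x) x@converged)

#' @rdname fitParams
#' @export
setGeneric("fitFlags", function(x) standardGeneric("fitFlags"))

#' @rdname fitParams
#' @export
setMethod("fitFlags", "ItcFit", function(x) x@flags)
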