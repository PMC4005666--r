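# S4 classes for the k-turn/k-junction toolkit. The central container is
# RNAStructure (parsed coordinates after optional RNA filtering); geometric
# abstractions are HelixFrame (a two-base-pair helix segment with its
# orthonormal triad) and RigidTransform (relative location/orientation of one
# frame in another's coordinate system). SearchPattern collects reference
# transforms with tolerances; KTurnAssignment maps structural roles to
# nucleotides; BindingParams/TitrationProtocol describe one-site ITC.

#' @import methods
NULL

.ATOM_COLS <- c("chain", "resno", "insert", "resname", "base",
                "elety", "x", "y", "z", "o")

setClass("RNAStructure",
  representation(atoms = "data.frame",
                 sourceId = "character",
                 modelIndex = "integer"))

setValidity("RNAStructure", function(object) {
  a <- object@atoms
  miss <- setdiff(.ATOM_COLS, names(a))
  if (length(miss) > 0L)
    return(paste("atoms table lacks columns:", paste(miss, collapse = ", ")))
  if (nrow(a) > 0L) {
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
      return("non-finite atom coordinates")
    if (any(!is.na(a$o) & (a$o < 0 | a$o > 1)))
      return("occupancy outside [0, 1]")
  }
  TRUE
})

setClass("HelixFrame",
  representation(origin = "numeric",
                 triad = "matrix",
                 pair1 = "character",
                 pair2 = "character"))

setValidity("HelixFrame", function(object) {
  if (length(object@origin) != 3L) return("origin must be numeric(3)")
  Tm <- object@triad
  if (!all(dim(Tm) == c(3L, 3L))) return("triad must be 3x3")
  g <- crossprod(Tm)
  if (max(abs(g - diag(3L))) > 1e-6) return("triad not orthonormal within 1e-6")
  if (det(Tm) < 0) return("triad not right-handed")
  TRUE
})

setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3L))) > 1e-9) return("rotation not orthogonal within 1e-9")
  if (abs(det(R) - 1) > 1e-9) return("rotation determinant != +1 within 1e-9")
  if (length(object@translation) != 3L) return("translation must be numeric(3)")
  TRUE
})

setClass("SearchPattern",
  representation(entries = "list",
                 translationTol = "numeric",
                 rotationTol = "numeric",
                 provenance = "data.frame"))

setValidity("SearchPattern", function(object) {
  if (length(object@entries) < 1L) return("pattern needs at least one entry")
  if (!all(vapply(object@entries, is, logical(1L), class2 = "RigidTransform")))
    return("entries must be RigidTransform objects")
  if (object@translationTol <= 0 || object@rotationTol <= 0)
    return("tolerances must be positive")
  TRUE
})

.KT_ROLES <- c("-2b", "-2n", "-1b", "-1n", "L1", "L1.1", "L2", "L3",
               "1b", "1n", "2b", "2n", "3b", "3n", "5b", "5n")
.KT_CORE <- c("-1n", "L1", "1b", "1n", "2b", "2n")

setClass("KTurnAssignment",
  representation(roles = "character",
                 completeCore = "logical",
                 notes = "character"))

setValidity("KTurnAssignment", function(object) {
  r <- object@roles
  if (is.null(names(r)) || any(!nzchar(names(r))))
    return("roles must be a named character vector (role -> nucleotide key)")
  bad <- setdiff(names(r), .KT_ROLES)
  if (length(bad) > 0L)
    return(paste("unknown role label(s):", paste(bad, collapse = ", ")))
  if (anyDuplicated(r)) return("role -> nucleotide mapping must be injective")
  if (anyDuplicated(names(r))) return("duplicate role labels")
  TRUE
})

setClass("ContactReport",
  representation(contacts = "data.frame", nClass = "character"))

setValidity("ContactReport", function(object) {
  if (!object@nClass %in% c("N1", "N3", "undetermined"))
    return("nClass must be N1, N3 or undetermined")
  d <- object@contacts$distance
  if (any(!is.na(d) & d < 0)) return("negative contact distance")
  TRUE
})

setClass("TitrationProtocol",
  representation(cellVolume = "numeric",
                 cellConc = "numeric",
                 syringeConc = "numeric",
                 injections = "numeric",
                 temperature = "numeric"))

setValidity("TitrationProtocol", function(object) {
  if (object@cellVolume <= 0) return("cellVolume must be > 0 (litres)")
  if (object@cellConc <= 0) return("cellConc must be > 0 (mol/L)")
  if (object@syringeConc <= 0) return("syringeConc must be > 0 (mol/L)")
  if (length(object@injections) < 1L || any(object@injections <= 0))
    return("injections must be positive volumes (litres)")
  if (object@temperature <= 0) return("temperature must be > 0 (kelvin)")
  TRUE
})

setClass("BindingParams",
  representation(n = "numeric", dH = "numeric", Ka = "numeric", Kd = "numeric",
                 dG = "numeric", dS = "numeric", T = "numeric",
                 energyUnit = "character"))

setValidity("BindingParams", function(object) {
  if (!is.na(object@n) && object@n <= 0) return("n must be > 0")
  if (!is.na(object@Ka)) {
    if (object@Ka <= 0) return("Ka must be > 0 (1/M)")
    if (!is.na(object@Kd) && abs(object@Kd * object@Ka - 1) > 1e-9)
      return("Kd must equal 1/Ka")
  }
  if (!is.na(object@dG) && !is.na(object@dS) && !is.na(object@dH)) {
    # entropy is carried in milli-units of the energy unit per kelvin
    # (J/K/mol alongside kJ/mol), the convention of calorimetric tables
    if (abs(object@dG - (object@dH - object@T * object@dS / 1000)) > 0.02)
      return("dG inconsistent with dH - T*dS beyond 0.02 energy units")
  }
  TRUE
})

setClass("ItcFit",
  representation(params = "BindingParams",
                 se = "numeric",
                 converged = "logical",
                 flags = "character",
                 residualNorm = "numeric",
                 nUsed = "integer",
                 fitted = "data.frame"))

# ---- show methods -----------------------------------------------------------

setMethod("show", "RNAStructure", function(object) {
  nt <- nucleotides(object)
  cat(sprintf("RNAStructure '%s' (model %d): %d atoms, %d nucleotides (%d complete), eligible = %s\n",
              object@sourceId, object@modelIndex, nrow(object@atoms),
              nrow(nt), sum(nt$complete), eligible(object)))
})

setMethod("show", "HelixFrame", function(object) {
  cat(sprintf("HelixFrame: pair1 [%s | %s], pair2 [%s | %s]\n",
              object@pair1[1L], object@pair1[2L],
              object@pair2[1L], object@pair2[2L]))
  cat(sprintf("  origin  %8.3f %8.3f %8.3f\n", object@origin[1L],
              object@origin[2L], object@origin[3L]))
  lab <- c("axis", "hbond", "normal")
  for (k in 1:3)
    cat(sprintf("  %-6s %8.4f %8.4f %8.4f\n", lab[k],
                object@triad[1L, k], object@triad[2L, k], object@triad[3L, k]))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: |t| = %.3f A, rotation angle = %.2f deg\n",
              .vnorm(object@translation), rotationAngle(object@rotation)))
})

setMethod("show", "SearchPattern", function(object) {
  cat(sprintf("SearchPattern: %d entr%s, translation tol %.2f A, rotation tol %.1f deg\n",
              length(object@entries),
              if (length(object@entries) == 1L) "y" else "ies",
              object@translationTol, object@rotationTol))
})

setMethod("show", "KTurnAssignment", function(object) {
  cat(sprintf("KTurnAssignment (%d roles, complete core = %s)\n",
              length(object@roles), object@completeCore))
  if (length(object@roles) > 0L) {
    ord <- order(match(names(object@roles), .KT_ROLES))
    for (i in ord)
      cat(sprintf("  %-5s -> %s\n", names(object@roles)[i], object@roles[i]))
  }
  if (length(object@notes) > 0L)
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "ContactReport", function(object) {
  cat(sprintf("ContactReport: class %s\n", object@nClass))
  print(object@contacts, row.names = FALSE)
})

setMethod("show", "TitrationProtocol", function(object) {
  cat(sprintf("TitrationProtocol: %.2f ml cell at %.1f uM, syringe %.1f uM, %d injections, T = %.2f K\n",
              object@cellVolume * 1e3, object@cellConc * 1e6,
              object@syringeConc * 1e6, length(object@injections),
              object@temperature))
})

setMethod("show", "BindingParams", function(object) {
  entUnit <- if (identical(object@energyUnit, "kcal/mol")) "cal/K/mol" else "J/K/mol"
  cat(sprintf("BindingParams (energies in %s, entropy in %s):\n",
              object@energyUnit, entUnit))
  cat(sprintf("  n = %.3f, dH = %.3f, Ka = %.4g 1/M (Kd = %.4g M)\n",
              object@n, object@dH, object@Ka, object@Kd))
  cat(sprintf("  dG = %.3f, dS = %.3f, T = %.2f K\n", object@dG, object@dS, object@T))
})

setMethod("show", "ItcFit", function(object) {
  cat(sprintf("ItcFit: converged = %s, injections used = %d, residual norm = %.4g\n",
              object@converged, object@nUsed, object@residualNorm))
  if (length(object@flags) > 0L) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
  show(object@params)
})
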