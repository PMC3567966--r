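#' @rdname DomainProfile-class
#' @param object A [DomainProfile-class] object.
#' @export
setGeneric("domainId", function(object) standardGeneric("domainId"))

#' @rdname DomainProfile-class
#' @export
setGeneric("profileLength", function(object) standardGeneric("profileLength"))

#' @rdname DomainProfile-class
#' @export
setGeneric("profileThreshold",
           function(object) standardGeneric("profileThreshold"))

#' @rdname DomainProfile-class
#' @export
setGeneric("isCalibrated", function(object) standardGeneric("isCalibrated"))

#' @rdname DomainProfile-class
#' @export
setGeneric("consensusResidues",
           function(object) standardGeneric("consensusResidues"))

#' @rdname DomainProfile-class
#' @export
setMethod("domainId", "DomainProfile", function(object) object@domainId)

#' @rdname DomainProfile-class
#' @export
setMethod("profileLength", "DomainProfile",
          function(object) ncol(object@scores))

#' @rdname DomainProfile-class
#' @export
setMethod("profileThreshold", "DomainProfile",
          function(object) object@threshold)

#' @rdname DomainProfile-class
#' @export
setMethod("isCalibrated", "DomainProfile",
          function(object) !is.na(object@threshold))

#' @rdname DomainProfile-class
#' @details \code{consensusResidues} returns the highest-scoring residue
#'   at each profile position.
#' @export
setMethod("consensusResidues", "DomainProfile", function(object) {
  aaAlphabet()[apply(object@scores, 2L, which.max)]
})

#' @rdname Architecture-class
#' @param object An [Architecture-class] object.
#' @export
setGeneric("proteinId", function(object) standardGeneric("proteinId"))

#' @rdname Architecture-class
#' @export
setGeneric("architectureHits",
           function(object) standardGeneric("architectureHits"))

#' @rdname Architecture-class
#' @export
setGeneric("architectureDomains",
           function(object) standardGeneric("architectureDomains"))

#' @rdname Architecture-class
#' @export
setGeneric("architectureMotifs",
           function(object) standardGeneric("architectureMotifs"))

#' @rdname Architecture-class
#' @export
setMethod("proteinId", "Architecture", function(object) object@proteinId)

#' @rdname Architecture-class
#' @export
setMethod("architectureHits", "Architecture", function(object) object@hits)

#' @rdname Architecture-class
#' @details \code{architectureDomains} returns the ordered domain labels.
#' @export
setMethod("architectureDomains", "Architecture",
          function(object) object@hits$domain_id)

#' @rdname Architecture-class
#' @export
setMethod("architectureMotifs", "Architecture",
          function(object) object@motifs)

#' @rdname HMCatalog-class
#' @param object An [HMCatalog-class] object.
#' @export
setGeneric("catalogMembers", function(object) standardGeneric("catalogMembers"))

#' @rdname HMCatalog-class
#' @export
setGeneric("catalogDecoys", function(object) standardGeneric("catalogDecoys"))

#' @rdname HMCatalog-class
#' @export
setGeneric("catalogOrgans", function(object) standardGeneric("catalogOrgans"))

#' @rdname HMCatalog-class
#' @export
setGeneric("catalogNotes", function(object) standardGeneric("catalogNotes"))

#' @rdname HMCatalog-class
#' @details \code{catalogMembers} returns the member rows (decoys
#'   excluded); \code{catalogDecoys} the decoy rows.
#' @export
setMethod("catalogMembers", "HMCatalog", function(object) {
  object@members[object@members$role == "member", , drop = FALSE]
})

#' @rdname HMCatalog-class
#' @export
setMethod("catalogDecoys", "HMCatalog", function(object) {
  object@members[object@members$role == "decoy", , drop = FALSE]
})

#' @rdname HMCatalog-class
#' @export
setMethod("catalogOrgans", "HMCatalog", function(object) object@organs)

#' @rdname HMCatalog-class
#' @export
setMethod("catalogNotes", "HMCatalog", function(object) object@notes)
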