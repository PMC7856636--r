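#' @include AllClasses.R
NULL

#' Number of atlas regions (graph nodes)
#' @param x a hubshift container.
#' @return integer count of regions.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' Number of subjects in a container
#' @param x a hubshift container.
#' @return integer count of subjects.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' Subject group labels
#' @param x a hubshift container.
#' @return character vector of group labels, one per subject.
#' @export
setGeneric("subjectGroups", function(x) standardGeneric("subjectGroups"))

#' Subject metadata table
#' @param x a hubshift container.
#' @return an `S4Vectors::DataFrame`, one row per subject.
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

setMethod("nRegions", "CohortDesign", function(x) x@nRegions)
setMethod("nRegions", "RoiTimeSeriesSet", function(x) {
  if (length(x@signals)) ncol(x@signals[[1L]]) else 0L
})
setMethod("nRegions", "ConnectomeSet", function(x) dim(x@r)[1L])
setMethod("nRegions", "BinaryGraphStack", function(x) {
  if (length(x@adjacency)) dim(x@adjacency[[1L]])[1L] else 0L
})

setMethod("nSubjects", "RoiTimeSeriesSet", function(x) length(x@signals))
setMethod("nSubjects", "ConnectomeSet", function(x) dim(x@r)[3L])
setMethod("nSubjects", "BinaryGraphStack", function(x) {
  if (length(x@adjacency)) dim(x@adjacency[[1L]])[3L] else 0L
})

setMethod("sampleData", "RoiTimeSeriesSet", function(x) x@colData)
setMethod("sampleData", "ConnectomeSet", function(x) x@colData)
setMethod("sampleData", "BinaryGraphStack", function(x) x@colData)

setMethod("subjectGroups", "RoiTimeSeriesSet", function(x) as.character(x@colData$group))
setMethod("subjectGroups", "ConnectomeSet", function(x) as.character(x@colData$group))
setMethod("subjectGroups", "BinaryGraphStack", function(x) as.character(x@colData$group))

#' Signal matrix of one subject
#' @param x a `RoiTimeSeriesSet`.
#' @param i subject index or id.
#' @return T x N numeric matrix.
#' @export
signalMatrix <- function(x, i) {
  stopifnot(is(x, "RoiTimeSeriesSet"))
  if (is.character(i)) i <- match(i, x@colData$subject_id)
  x@signals[[i]]
}

#' Censor mask of one subject (TRUE = usable volume)
#' @param x a `RoiTimeSeriesSet`.
#' @param i subject index or id.
#' @return logical vector.
#' @export
censorMask <- function(x, i) {
  stopifnot(is(x, "RoiTimeSeriesSet"))
  if (is.character(i)) i <- match(i, x@colData$subject_id)
  x@censor[[i]]
}

#' Correlation matrix of one subject
#' @param x a `ConnectomeSet`.
#' @param i subject index.
#' @return N x N numeric matrix.
#' @export
connectivityMatrix <- function(x, i) {
  stopifnot(is(x, "ConnectomeSet"))
  x@r[, , i]
}

#' Densities available in a graph stack
#' @param x a `BinaryGraphStack`.
#' @return numeric vector of link densities.
#' @export
graphDensities <- function(x) {
  stopifnot(is(x, "BinaryGraphStack"))
  x@densities
}

#' Adjacency matrix of one subject at one density
#' @param x a `BinaryGraphStack`.
#' @param density one of `graphDensities(x)`.
#' @param i subject index.
#' @return N x N logical matrix.
#' @export
adjacencyMatrix <- function(x, density, i) {
  stopifnot(is(x, "BinaryGraphStack"))
  k <- match(TRUE, abs(x@densities - density) < 1e-9)
  if (is.na(k)) stop("density ", density, " not present in the stack")
  x@adjacency[[k]][, , i]
}

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign:", object@nRegions, "regions,",
      object@nVolumes, "volumes @ TR", object@trSeconds, "s\n")
  cat("  groups (patient/control/holdout):",
      paste(object@groupSizes[c("patient", "control", "holdout")], collapse = "/"), "\n")
  cat("  modules:", length(unique(object@moduleAssignment)),
      "| hubs:", length(object@hubSet),
      "| kTrue:", object@kTrue,
      "| switch nodes:", length(object@switchSet), "\n")
  cat("  pain weights on", length(object@betaPain), "regions; noiseSd",
      object@noiseSd, "; motionRate", object@motionRate, "; seed", object@seed, "\n")
})

setMethod("show", "RoiTimeSeriesSet", function(object) {
  cat("RoiTimeSeriesSet:", nSubjects(object), "subjects x",
      nRegions(object), "regions, TR", object@trSeconds, "s\n")
  if (nSubjects(object)) {
    tt <- vapply(object@signals, nrow, 1L)
    cat("  volumes:", if (length(unique(tt)) == 1L) tt[1L] else
        paste0(min(tt), "-", max(tt)), "\n")
  }
  cat("  groups:", paste(sprintf("%s=%d", names(table(subjectGroups(object))),
      table(subjectGroups(object))), collapse = ", "), "\n")
  if (length(object@log)) cat("  steps:", paste(object@log, collapse = " -> "), "\n")
})

setMethod("show", "ConnectomeSet", function(object) {
  cat("ConnectomeSet:", nSubjects(object), "subjects,",
      nRegions(object), "x", nRegions(object), "Pearson matrices\n")
  cat("  usable volumes:", paste(range(object@usableVolumes), collapse = "-"), "\n")
})

setMethod("show", "BinaryGraphStack", function(object) {
  cat("BinaryGraphStack:", nSubjects(object), "subjects x",
      length(object@densities), "densities (",
      paste(format(object@densities), collapse = ", "), ")\n")
})
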