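#' Parcellation schemes
#'
#' A parcellation scheme is the ordered lookup table of ROI labels that fixes
#' the feature ordering of every connectivity matrix and feature table in the
#' pipeline. Each label carries its anatomical structure (cerebrum or
#' cerebellum), its functional network name, its hemisphere, and the collapsed
#' bilateral "macro network" used when coefficient vectors are compared across
#' cohorts.
#'
#' @name parcellation
NULL

.yeo17 <- c(
  "VisCent", "VisPeri", "SomMotA", "SomMotB", "DorsAttnA", "DorsAttnB",
  "SalVentAttnA", "SalVentAttnB", "LimbicA", "LimbicB", "ContA", "ContB",
  "ContC", "DefaultA", "DefaultB", "DefaultC", "TempPar"
)

# Yeo 17 -> 7 correspondence; TempPar folds into DefaultMode.
.yeo17_macro <- c(
  VisCent = "Visual", VisPeri = "Visual",
  SomMotA = "Somatomotor", SomMotB = "Somatomotor",
  DorsAttnA = "DorsalAttention", DorsAttnB = "DorsalAttention",
  SalVentAttnA = "VentralAttention", SalVentAttnB = "VentralAttention",
  LimbicA = "Limbic", LimbicB = "Limbic",
  ContA = "Control", ContB = "Control", ContC = "Control",
  DefaultA = "DefaultMode", DefaultB = "DefaultMode", DefaultC = "DefaultMode",
  TempPar = "DefaultMode"
)

.buckner7 <- c(
  "Visual", "Somatomotor", "DorsalAttention", "VentralAttention",
  "Limbic", "Control", "DefaultMode"
)

#' Default 48-label cerebellar-cerebral parcellation
#'
#' Builds the default scheme combining a 17-network cerebral cortical
#' parcellation with a 7-network cerebellar parcellation, each split by
#' hemisphere: 17 x 2 + 7 x 2 = 48 ROI labels. Cerebral labels come first
#' (network-major, left before right), then cerebellar labels. Macro networks
#' collapse hemispheres and cortical subdivisions to 7 bilateral networks per
#' structure, kept distinct between cerebrum and cerebellum.
#'
#' @return A `parcellation` data frame with columns `label_id`, `roi_name`,
#'   `structure`, `network_name`, `hemisphere`, `macro_network`.
#' @examples
#' scheme <- default_parcellation()
#' count_rois(scheme)  # 48
#' @export
default_parcellation <- function() {
  cx <- data.frame(
    structure = "cerebrum",
    network_name = rep(.yeo17, each = 2L),
    hemisphere = rep(c("L", "R"), times = 17L),
    stringsAsFactors = FALSE
  )
  cx$macro_network <- paste0("Cerebrum-", .yeo17_macro[cx$network_name])
  cb <- data.frame(
    structure = "cerebellum",
    network_name = rep(.buckner7, each = 2L),
    hemisphere = rep(c("L", "R"), times = 7L),
    stringsAsFactors = FALSE
  )
  cb$macro_network <- paste0("Cerebellum-", cb$network_name)
  scheme <- rbind(cx, cb)
  scheme$label_id <- seq_len(nrow(scheme))
  prefix <- ifelse(scheme$structure == "cerebrum", "Cx", "Cb")
  scheme$roi_name <- paste(prefix, scheme$network_name, scheme$hemisphere,
                           sep = "_")
  scheme <- scheme[, c("label_id", "roi_name", "structure", "network_name",
                       "hemisphere", "macro_network")]
  class(scheme) <- c("parcellation", "data.frame")
  validate_parcellation(scheme)
  scheme
}

#' Validate a parcellation scheme
#'
#' Checks the structural invariants: unique contiguous 1-based label ids,
#' recognised structure and hemisphere codes, and a macro network for every
#' label.
#'
#' @param scheme A parcellation data frame.
#' @return The scheme, invisibly, if valid; otherwise an error.
#' @export
validate_parcellation <- function(scheme) {
  required <- c("label_id", "roi_name", "structure", "network_name",
                "hemisphere", "macro_network")
  missing <- setdiff(required, names(scheme))
  if (length(missing) > 0L)
    stop("parcellation is missing columns: ", paste(missing, collapse = ", "))
  n <- nrow(scheme)
  if (n > 0L && !identical(as.integer(scheme$label_id), seq_len(n)))
    stop("label_id must be contiguous 1..n in order")
  if (!all(scheme$structure %in% c("cerebrum", "cerebellum")))
    stop("structure must be 'cerebrum' or 'cerebellum'")
  if (!all(scheme$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  if (anyNA(scheme$macro_network) || any(!nzchar(scheme$macro_network)))
    stop("every label needs a macro_network")
  if (anyDuplicated(scheme$roi_name))
    stop("roi_name values must be unique")
  invisible(scheme)
}

#' Number of ROIs in a scheme
#'
#' @param scheme A parcellation data frame.
#' @return Integer count of labels.
#' @export
count_rois <- function(scheme) {
  validate_parcellation(scheme)
  nrow(scheme)
}

#' Restrict a scheme to one structure
#'
#' Subsets the labels to `cerebrum` or `cerebellum` and renumbers label ids
#' contiguously so the result is itself a valid scheme.
#'
#' @param scheme A parcellation data frame.
#' @param structure `"cerebrum"` or `"cerebellum"`.
#' @return A parcellation restricted to the requested structure.
#' @export
restrict_parcellation <- function(scheme, structure) {
  structure <- match.arg(structure, c("cerebrum", "cerebellum"))
  out <- scheme[scheme$structure == structure, , drop = FALSE]
  out$label_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("parcellation", "data.frame")
  out
}

#' Feature identifiers for all ROI pairs
#'
#' Upper-triangle (i < j), row-major in parcellation order; this ordering is
#' the contract every feature table in the pipeline follows.
#'
#' @param scheme A parcellation data frame.
#' @return Character vector of "ROIi__ROIj" ids, length n(n-1)/2.
#' @export
roi_pair_ids <- function(scheme) {
  validate_parcellation(scheme)
  n <- nrow(scheme)
  if (n < 2L) return(character(0))
  idx <- upper_tri_pairs(n)
  paste0(scheme$roi_name[idx[, 1L]], "__", scheme$roi_name[idx[, 2L]])
}

#' @keywords internal
upper_tri_pairs <- function(n) {
  # row-major upper triangle: (1,2),(1,3),...,(1,n),(2,3),...
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n),
              use.names = FALSE)
  cbind(i = i, j = j)
}

#' Read / write a parcellation TSV
#'
#' The on-disk format is a tab-separated table with columns `label_id`,
#' `roi_name`, `structure`, `network_name`, `hemisphere`, `macro_network`.
#'
#' @param path File path.
#' @param scheme A parcellation data frame (for writing).
#' @return `read_parcellation` returns a validated `parcellation`;
#'   `write_parcellation` returns `path` invisibly.
#' @export
read_parcellation <- function(path) {
  scheme <- utils::read.delim(path, stringsAsFactors = FALSE)
  scheme$label_id <- as.integer(scheme$label_id)
  class(scheme) <- c("parcellation", "data.frame")
  validate_parcellation(scheme)
  scheme
}

#' @rdname read_parcellation
#' @export
write_parcellation <- function(scheme, path) {
  validate_parcellation(scheme)
  utils::write.table(scheme, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
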