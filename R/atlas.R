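#' The four social brain networks
#'
#' Canonical network labels, ordered from lower sensory to higher associative
#' processing levels.
#'
#' @format Character vector of length 4.
#' @export
SB_NETWORKS <- c("visual_sensory", "limbic", "intermediate",
                 "higher_associative")

# region_id blocks of the default atlas: 1-6 visual sensory, 7-14 limbic,
# 15-25 intermediate, 26-36 higher associative
SB_NETWORK_SIZES <- c(visual_sensory = 6L, limbic = 8L, intermediate = 11L,
                      higher_associative = 11L)

#' Load a social brain atlas definition
#'
#' Reads and validates a 36-region atlas table. The packaged default
#' describes the social brain atlas: 36 regions named by their standard
#' abbreviations (pSTS, FG, MT-V5, AM, HC, NAC, vmPFC, rACC, AI, aMCC, IFG,
#' SMA, SMG, Cereb, TP, dmPFC, MTG, pMCC, FP, TPJ, PCC, Prec, with `_L`/`_R`
#' hemisphere suffixes), partitioned into four networks with block sizes
#' 6/8/11/11. The default file's MNI coordinate column is a synthetic
#' approximation of the published peak locations, shipped so that the
#' geometric pipeline is runnable end to end; analyses of real data should
#' supply the deposited coordinates via `path`.
#'
#' @param path Path to an atlas CSV with columns
#'   `region_id,name,hemisphere,network,x,y,z`, or `"default"` for the
#'   packaged atlas.
#' @param strict If `TRUE` (default) the table must contain exactly 36
#'   regions; set `FALSE` to load reduced test atlases.
#' @return An object of class `sb_atlas`: a data frame of regions ordered by
#'   `region_id`, with attribute `source`.
#' @export
load_atlas <- function(path = "default", strict = TRUE) {
  if (identical(path, "default")) {
    file <- system.file("extdata", "social_brain_atlas_synthetic.csv",
                        package = "sbhbm", mustWork = TRUE)
    source <- "packaged-default"
  } else {
    file <- path
    source <- path
    if (!file.exists(file)) {
      stop("atlas file not found: ", file, call. = FALSE)
    }
  }
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  required <- c("region_id", "name", "hemisphere", "network", "x", "y", "z")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("atlas table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_atlas(tab, strict = strict, source = source)
}

#' Construct an atlas from an in-memory table
#'
#' @param tab Data frame with the atlas columns (see [load_atlas()]).
#' @param strict Require exactly 36 regions.
#' @param source Provenance string stored on the object.
#' @return `sb_atlas` object.
#' @export
validate_atlas <- function(tab, strict = TRUE, source = "in-memory") {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (anyNA(tab$region_id) || !is.numeric(tab$region_id)) {
    stop("atlas region_id must be numeric and non-missing", call. = FALSE)
  }
  dup <- tab$region_id[duplicated(tab$region_id)]
  if (length(dup) > 0) {
    stop("duplicate region_id in atlas: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (strict) {
    if (nrow(tab) != 36L) {
      stop("atlas must define exactly 36 regions, got ", nrow(tab),
           call. = FALSE)
    }
    if (!setequal(tab$region_id, 1:36)) {
      stop("atlas region_id values must cover exactly 1..36", call. = FALSE)
    }
  }
  bad_net <- setdiff(unique(tab$network), SB_NETWORKS)
  if (length(bad_net) > 0) {
    rows <- which(tab$network %in% bad_net)
    stop("unknown network label(s) ", paste(bad_net, collapse = ", "),
         " in atlas row(s) ", paste(rows, collapse = ", "), call. = FALSE)
  }
  bad_hemi <- setdiff(unique(tab$hemisphere), c("L", "R", "midline"))
  if (length(bad_hemi) > 0) {
    stop("unknown hemisphere label(s): ",
         paste(bad_hemi, collapse = ", "), call. = FALSE)
  }
  for (col in c("x", "y", "z")) {
    if (!is.numeric(tab[[col]]) || anyNA(tab[[col]])) {
      stop("atlas coordinate column '", col,
           "' must be numeric and non-missing", call. = FALSE)
    }
  }
  if (anyDuplicated(tab$name)) {
    stop("duplicate region names in atlas", call. = FALSE)
  }
  tab <- tab[order(tab$region_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab$region_id <- as.integer(tab$region_id)
  structure(tab, source = source, class = c("sb_atlas", "data.frame"))
}

#' @export
print.sb_atlas <- function(x, ...) {
  cat("Social brain atlas (", nrow(x), " regions, source: ",
      attr(x, "source"), ")\n", sep = "")
  sizes <- table(factor(x$network, levels = SB_NETWORKS))
  cat("Networks:",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Network label of a region
#'
#' @param atlas `sb_atlas` object.
#' @param region_id Integer region identifier(s).
#' @return Character vector of network labels.
#' @export
network_of <- function(atlas, region_id) {
  stopifnot(inherits(atlas, "sb_atlas"))
  idx <- match(region_id, atlas$region_id)
  if (anyNA(idx)) {
    stop("region_id out of range: ",
         paste(region_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  atlas$network[idx]
}

#' Integer network index (1..4) of every atlas region
#'
#' Utility used by the hierarchical model to map region coefficients to
#' their network-level parents.
#'
#' @param atlas `sb_atlas` object.
#' @return Integer vector, one entry per region, indexing into
#'   [SB_NETWORKS].
#' @export
network_index <- function(atlas) {
  match(atlas$network, SB_NETWORKS)
}

#' Sizes of the network partition of an atlas
#'
#' @param atlas `sb_atlas` object.
#' @return Named integer vector over the four networks.
#' @export
network_sizes <- function(atlas) {
  sizes <- table(factor(atlas$network, levels = SB_NETWORKS))
  stats::setNames(as.integer(sizes), names(sizes))
}
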