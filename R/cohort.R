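#' Social indices analyzed by the pipeline
#'
#' @format Character vector: `"support"`, `"household"`, `"friendship"`.
#' @export
SB_INDICES <- c("support", "household", "friendship")

index_column <- function(social_index) {
  switch(match.arg(social_index, SB_INDICES),
         support = "social_support",
         household = "household_size",
         friendship = "friendship_satisfaction")
}

#' Group labels for a social index
#'
#' Groups encode sex crossed with the dichotomized trait:
#' 0 = male/low, 1 = male/high, 2 = female/low, 3 = female/high. "Low" and
#' "high" mean less/more frequent social support, lives alone / lives with
#' others, and unhappy/happy with friendships, respectively.
#'
#' @param social_index One of [SB_INDICES].
#' @return Character vector of 4 labels, ordered by group id 0..3.
#' @export
group_labels <- function(social_index) {
  trait <- switch(match.arg(social_index, SB_INDICES),
                  support = c("less_support", "more_support"),
                  household = c("lives_alone", "lives_with_others"),
                  friendship = c("unhappy_friendships", "happy_friendships"))
  as.vector(outer(trait, c("male", "female"),
                  function(t, s) paste(s, t, sep = "_")))
}

NON_ANSWERS <- c("do_not_know", "prefer_not_to_answer", "")

parse_item <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  x[x %in% NON_ANSWERS] <- NA
  suppressWarnings(as.numeric(x))
}

#' Read a phenotype CSV
#'
#' Expected header: `participant_id,sex,age,social_support,household_size,
#' friendship_satisfaction,body_mass,head_size_scaling`. Non-answers to the
#' social items are the literal strings `do_not_know` /
#' `prefer_not_to_answer` or empty fields; they are preserved as `NA` until
#' [clean_responses()].
#'
#' @param path CSV path.
#' @return Data frame of participant records.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  required <- c("participant_id", "sex", "age", "social_support",
                "household_size", "friendship_satisfaction", "body_mass",
                "head_size_scaling")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("social_support", "household_size",
                "friendship_satisfaction")) {
    df[[col]] <- parse_item(df[[col]])
  }
  df
}

#' Remove participants unusable for one social index
#'
#' Drops records with a non-answer or missing value on the given social
#' item, or with missing sex, age, body mass, or head-size scaling, and
#' records whose sex is not male/female as recorded. Removal counts are
#' attached as attribute `removed` and logged via `message()`.
#'
#' @param records Phenotype data frame (see [read_phenotypes()]).
#' @param social_index One of [SB_INDICES].
#' @param quiet Suppress the log message.
#' @return Filtered data frame.
#' @export
clean_responses <- function(records, social_index, quiet = FALSE) {
  col <- index_column(social_index)
  n0 <- nrow(records)
  keep <- !is.na(parse_item(records[[col]])) &
    records$sex %in% c("male", "female") &
    !is.na(suppressWarnings(as.numeric(records$age))) &
    !is.na(suppressWarnings(as.numeric(records$body_mass))) &
    !is.na(suppressWarnings(as.numeric(records$head_size_scaling)))
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("all participants removed while cleaning index '", social_index,
         "'", call. = FALSE)
  }
  removed <- n0 - nrow(out)
  if (!quiet && removed > 0) {
    message("clean_responses[", social_index, "]: removed ", removed,
            " of ", n0, " participants")
  }
  attr(out, "removed") <- removed
  out
}

#' Median-split a quantitative or ordinal vector
#'
#' High group: strictly greater than the sample median; ties at the median
#' go to the low group (deterministic rule; the tie mass is attached as
#' attribute `tie_mass` so group balance can be audited).
#'
#' @param values Numeric vector without missing values, at least two
#'   distinct values.
#' @return Logical vector, `TRUE` = high group, with attributes `median`
#'   and `tie_mass`.
#' @export
median_split <- function(values) {
  if (anyNA(values)) stop("median_split: missing values", call. = FALSE)
  if (length(unique(values)) < 2L) {
    stop("median_split: fewer than 2 distinct values", call. = FALSE)
  }
  med <- stats::median(values)
  high <- values > med
  structure(high, median = med, tie_mass = sum(values == med))
}

#' Dichotomize household size as lives alone vs with others
#'
#' @param sizes Positive integer vector of household sizes (including the
#'   respondent).
#' @return Logical vector, `TRUE` = lives with others (size >= 2).
#' @export
dichotomize_household <- function(sizes) {
  if (anyNA(sizes)) stop("household sizes contain missing values",
                         call. = FALSE)
  if (any(sizes < 1)) {
    stop("household sizes must be >= 1 (respondent included)",
         call. = FALSE)
  }
  sizes >= 2
}

#' Assign sex-by-trait group ids
#'
#' `group_id = 2 * (sex == "female") + (trait == high)`, i.e. 0 = male/low,
#' 1 = male/high, 2 = female/low, 3 = female/high.
#'
#' @param sex Character vector of `"male"` / `"female"`.
#' @param trait_high Logical vector, `TRUE` = high category.
#' @return Integer vector of group ids in 0..3.
#' @export
assign_groups <- function(sex, trait_high) {
  stopifnot(length(sex) == length(trait_high))
  bad <- setdiff(unique(sex), c("male", "female"))
  if (length(bad) > 0) {
    stop("unknown sex code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  as.integer(2L * (sex == "female") + as.integer(trait_high))
}

#' Construct a validated design-matrix object
#'
#' @param X n x J matrix of z-scored region volumes.
#' @param y Length-n z-scored age target.
#' @param C n x P matrix of z-scored confounds (may have 0 columns).
#' @param g Integer group ids in 0..3 (or 0..(n_groups-1)).
#' @param network Integer vector of length J mapping each region column to
#'   its network (1..4); regions in column order.
#' @param social_index Label of the social index this design targets.
#' @param participant_id Optional ids, length n.
#' @param n_groups Number of groups (default 4).
#' @return Object of class `sb_design`.
#' @export
new_design <- function(X, y, C, g, network, social_index = "support",
                       participant_id = NULL, n_groups = 4L) {
  X <- as.matrix(X); C <- as.matrix(C)
  n <- nrow(X)
  stopifnot(length(y) == n, nrow(C) == n, length(g) == n,
            length(network) == ncol(X))
  if (!all(is.finite(X)) || !all(is.finite(y)) ||
      (ncol(C) > 0 && !all(is.finite(C)))) {
    stop("design contains missing or non-finite values", call. = FALSE)
  }
  g <- as.integer(g)
  if (any(g < 0L | g >= n_groups)) {
    stop("group ids must lie in 0..", n_groups - 1L, call. = FALSE)
  }
  if (n > 0L) {
    counts <- tabulate(g + 1L, nbins = n_groups)
    if (any(counts == 0L)) {
      stop("empty group(s): ",
           paste(which(counts == 0L) - 1L, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(X = X, y = as.numeric(y), C = C, g = g,
                 network = as.integer(network),
                 social_index = social_index,
                 participant_id = participant_id,
                 n_groups = as.integer(n_groups)),
            class = "sb_design")
}

#' @export
print.sb_design <- function(x, ...) {
  cat("sb_design [", x$social_index, "]: n =", nrow(x$X),
      ", regions =", ncol(x$X), ", confounds =", ncol(x$C), "\n")
  if (nrow(x$X) > 0) {
    cat("group sizes:",
        paste(tabulate(x$g + 1L, x$n_groups), collapse = "/"), "\n")
  }
  invisible(x)
}

#' Assemble the model design for one social index
#'
#' Cleans the phenotype records for the index, dichotomizes the social item
#' (median split for support and friendship satisfaction; lives alone vs
#' with others for household size, unless `household_rule = "median"`),
#' assigns sex-by-trait groups, aligns records with the region-volume
#' matrix by participant id, and z-scores volumes, age and confounds.
#' Row order is canonicalized by sorting participant ids, so shuffled
#' inputs yield identical designs.
#'
#' @param volumes `sb_region_volumes` object.
#' @param records Phenotype data frame.
#' @param social_index One of [SB_INDICES].
#' @param atlas Atlas supplying the region-to-network map; region names
#'   must match the volume matrix columns. Default: packaged atlas.
#' @param household_rule `"alone"` (default; lives alone vs with others) or
#'   `"median"` (literal median split of household size).
#' @param quiet Suppress cleaning log.
#' @return `sb_design` object.
#' @export
build_design <- function(volumes, records, social_index,
                         atlas = load_atlas("default"),
                         household_rule = c("alone", "median"),
                         quiet = FALSE) {
  stopifnot(inherits(volumes, "sb_region_volumes"))
  social_index <- match.arg(social_index, SB_INDICES)
  household_rule <- match.arg(household_rule)
  if (!identical(colnames(volumes$raw), atlas$name)) {
    stop("volume matrix columns do not match atlas region names",
         call. = FALSE)
  }
  rec <- clean_responses(records, social_index, quiet = quiet)
  ids <- as.character(rec$participant_id)
  missing_ids <- setdiff(ids, rownames(volumes$raw))
  if (length(missing_ids) > 0) {
    stop("participant id(s) missing from volume matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) " ..." else "", call. = FALSE)
  }
  ord <- order(ids)
  rec <- rec[ord, , drop = FALSE]
  ids <- ids[ord]
  col <- index_column(social_index)
  item <- parse_item(rec[[col]])
  trait_high <- if (social_index == "household" &&
                    household_rule == "alone") {
    dichotomize_household(item)
  } else {
    as.logical(median_split(item))
  }
  g <- assign_groups(rec$sex, trait_high)
  X <- zscore_columns(volumes$raw[ids, , drop = FALSE])
  y <- as.vector(zscore_columns(matrix(as.numeric(rec$age))))
  C <- zscore_columns(cbind(body_mass = as.numeric(rec$body_mass),
                            head_size_scaling =
                              as.numeric(rec$head_size_scaling)))
  new_design(X, y, C, g, network = network_index(atlas),
             social_index = social_index, participant_id = ids)
}
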