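#' Specimen-level trait tables
#'
#' A trait table is a plain `data.frame` with the metadata columns
#' `specimen_id`, `species`, `sex`, `locality` followed by `p` numeric trait
#' columns (by convention `d1..dp`; `p = 21` for the default skull distance
#' set). All package functions that consume specimen data take this layout.
#'
#' @param df data.frame to validate.
#' @return `df`, invisibly, after validation.
#' @export
validate_trait_table <- function(df) {
  meta <- c("specimen_id", "species", "sex", "locality")
  missing <- setdiff(meta, names(df))
  if (length(missing) > 0) {
    stop("trait table is missing metadata columns: ",
         paste(missing, collapse = ", "))
  }
  tn <- trait_names(df)
  if (length(tn) < 2) stop("trait table needs at least 2 trait columns")
  vals <- as.matrix(df[tn])
  if (!is.numeric(vals)) stop("trait columns must be numeric")
  if (anyNA(vals)) {
    bad <- df$specimen_id[rowSums(is.na(vals)) > 0]
    stop("missing trait values for specimens: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(df)
}

#' Trait column names of a trait table
#'
#' @param df a trait table.
#' @return character vector of trait column names (all non-metadata columns).
#' @export
trait_names <- function(df) {
  setdiff(names(df), c("specimen_id", "species", "sex", "locality"))
}

#' Numeric trait matrix of a trait table
#'
#' @param df a trait table.
#' @return numeric matrix, one row per specimen, with trait column names.
#' @export
trait_matrix <- function(df) {
  m <- as.matrix(df[trait_names(df)])
  rownames(m) <- df$specimen_id
  m
}

#' Landmark pairs defining the default skull distance set
#'
#' The 21 inter-landmark distances measured on a 22-landmark skull
#' configuration. Distance `d_j` is the Euclidean distance between the two
#' landmarks of row `j`.
#'
#' @return integer matrix with 21 rows and columns `from`, `to`; rownames
#'   `d1..d21`.
#' @export
skull_distance_pairs <- function() {
  pairs <- matrix(c(
    1, 2,    # d1  nasal
    2, 3,    # d2  frontoparietal
    1, 4,    # d3  nasal
    1, 5,    # d4  nasal
    5, 6,    # d5  frontoparietal
    4, 6,    # d6  orbit
    6, 8,    # d7  squamosal
    7, 9,    # d8  occipital
    1, 10,   # d9  prenasal
    1, 11,   # d10 nasal
    5, 11,   # d11 nasal
    10, 12,  # d12 maxilla
    8, 12,   # d13 squamosal
    13, 14,  # d14 parasphenoid
    13, 20,  # d15 parasphenoid
    15, 16,  # d16 premaxilla
    16, 17,  # d17 maxilla
    17, 18,  # d18 neopalatine
    17, 19,  # d19 pterygoid
    19, 20,  # d20 pterygoid
    21, 22), # d21 mandible
    ncol = 2, byrow = TRUE,
    dimnames = list(paste0("d", 1:21), c("from", "to")))
  pairs
}

#' Compute inter-landmark distances from a 3D landmark table
#'
#' Converts per-specimen landmark coordinates into a trait table of Euclidean
#' inter-landmark distances. The landmark table is long format:
#' `specimen_id, landmark, x, y, z` with 1-based landmark ids, optionally
#' carrying `species`, `sex`, `locality` (constant within specimen).
#'
#' @param landmarks data.frame with columns `specimen_id`, `landmark`,
#'   `x`, `y`, `z` and optional metadata columns.
#' @param pairs two-column integer matrix of landmark id pairs; rownames are
#'   used as trait names. Defaults to [skull_distance_pairs()].
#' @return a trait table with one distance column per pair.
#' @export
distances_from_landmarks <- function(landmarks, pairs = skull_distance_pairs()) {
  need <- c("specimen_id", "landmark", "x", "y", "z")
  missing <- setdiff(need, names(landmarks))
  if (length(missing) > 0) {
    stop("landmark table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!all(is.finite(as.matrix(landmarks[c("x", "y", "z")])))) {
    stop("non-finite landmark coordinates")
  }
  pairs <- as.matrix(pairs)
  if (is.null(rownames(pairs))) rownames(pairs) <- paste0("d", seq_len(nrow(pairs)))
  specs <- unique(landmarks$specimen_id)
  meta_cols <- intersect(c("species", "sex", "locality"), names(landmarks))
  out <- lapply(specs, function(s) {
    sub <- landmarks[landmarks$specimen_id == s, , drop = FALSE]
    coords <- as.matrix(sub[c("x", "y", "z")])
    rownames(coords) <- as.character(sub$landmark)
    needed <- unique(as.vector(pairs))
    absent <- setdiff(as.character(needed), rownames(coords))
    if (length(absent) > 0) {
      stop("specimen ", s, " is missing landmark(s): ",
           paste(absent, collapse = ", "))
    }
    d <- vapply(seq_len(nrow(pairs)), function(j) {
      a <- coords[as.character(pairs[j, 1]), ]
      b <- coords[as.character(pairs[j, 2]), ]
      sqrt(sum((a - b)^2))
    }, numeric(1))
    row <- data.frame(specimen_id = s, stringsAsFactors = FALSE)
    for (mc in c("species", "sex", "locality")) {
      row[[mc]] <- if (mc %in% meta_cols) as.character(sub[[mc]][1]) else NA_character_
    }
    row[rownames(pairs)] <- as.list(d)
    row
  })
  do.call(rbind, out)
}

#' Intraclass-correlation repeatability of repeated measurements
#'
#' Lessells & Boag repeatability from a one-way ANOVA among specimens with
#' two replicate measurements per specimen:
#' `r = s2_A / (s2_A + s2_W)` with `s2_A = (MS_among - MS_within) / 2`.
#' Negative variance-component estimates are clipped to zero (with the
#' `clipped` attribute set), the standard variance-component convention.
#'
#' @param rep1,rep2 trait tables holding the first and second measurement of
#'   the same specimens (matched by `specimen_id`).
#' @return named numeric vector of per-trait repeatabilities in `[0, 1]`,
#'   with attribute `clipped`: logical vector marking traits whose raw
#'   estimate was negative.
#' @export
trait_repeatability <- function(rep1, rep2) {
  validate_trait_table(rep1)
  validate_trait_table(rep2)
  if (nrow(rep1) < 2) stop("need at least 2 specimens for repeatability")
  if (!setequal(rep1$specimen_id, rep2$specimen_id)) {
    stop("the two replicate tables must contain the same specimens")
  }
  rep2 <- rep2[match(rep1$specimen_id, rep2$specimen_id), , drop = FALSE]
  tn <- intersect(trait_names(rep1), trait_names(rep2))
  m1 <- as.matrix(rep1[tn])
  m2 <- as.matrix(rep2[tn])
  n <- nrow(m1)
  r <- numeric(length(tn))
  clipped <- logical(length(tn))
  for (j in seq_along(tn)) {
    y <- c(m1[, j], m2[, j])
    grand <- mean(y)
    means <- (m1[, j] + m2[, j]) / 2
    ms_among <- 2 * sum((means - grand)^2) / (n - 1)
    ms_within <- sum((m1[, j] - means)^2 + (m2[, j] - means)^2) / n
    s2a <- (ms_among - ms_within) / 2
    if (s2a < 0) {
      clipped[j] <- TRUE
      s2a <- 0
    }
    r[j] <- if (s2a + ms_within == 0) 1 else s2a / (s2a + ms_within)
  }
  names(r) <- tn
  if (any(clipped)) {
    warning("negative repeatability estimate clipped to 0 for: ",
            paste(tn[clipped], collapse = ", "))
  }
  attr(r, "clipped") <- stats::setNames(clipped, tn)
  r
}
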