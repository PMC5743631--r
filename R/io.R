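#' Read and write trait tables
#'
#' Trait CSV layout: header `specimen_id,species,sex,locality,d1,...,dp`.
#'
#' @param path CSV file path.
#' @return [read_trait_table()]: a validated trait table.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = c(specimen_id = "character",
                                       species = "character",
                                       sex = "character",
                                       locality = "character"))
  validate_trait_table(df)
  df
}

#' @rdname read_trait_table
#' @param df trait table to write.
#' @export
write_trait_table <- function(df, path) {
  validate_trait_table(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format landmark table
#'
#' Landmark CSV layout: `specimen_id,landmark,x,y,z` with 1-based landmark
#' ids, plus optional `species`, `sex`, `locality`.
#'
#' @param path CSV file path.
#' @return data.frame ready for [distances_from_landmarks()].
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "landmark", "x", "y", "z")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(path, " is missing columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Write / read a P-matrix as CSV plus JSON sidecar
#'
#' The matrix (covariance or correlation per `kind_matrix`) goes to
#' `<path>.csv` with trait-name header and index; metadata (`species`, `n`,
#' `df`, `kind`, `matrix`) to `<path>.json`.
#'
#' @param P a [pmatrix].
#' @param path file stem (no extension).
#' @param matrix which matrix to write, `"cov"` or `"cor"`.
#' @return the stem, invisibly.
#' @export
write_pmatrix <- function(P, path, matrix = c("cov", "cor")) {
  matrix <- match.arg(matrix)
  stopifnot(inherits(P, "pmatrix"))
  M <- P[[matrix]]
  utils::write.csv(as.data.frame(M), paste0(path, ".csv"), quote = FALSE)
  jsonlite::write_json(
    list(species = P$species, n = P$n, df = P$df, kind = P$kind,
         matrix = matrix),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pmatrix
#' @export
read_pmatrix <- function(path) {
  M <- as.matrix(utils::read.csv(paste0(path, ".csv"), row.names = 1,
                                 check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (identical(meta$matrix, "cor")) {
    stop("sidecar marks a correlation matrix; a P-matrix needs the covariance")
  }
  pmatrix(M, n = meta$n, df = meta$df, species = meta$species,
          kind = meta$kind)
}

#' Read and write modularity models as JSON
#'
#' JSON dialect: a list of objects
#' `{"name": ..., "modules": {"snout": ["d9", ...], ...}, "background":
#' [...]}` (a single object is also accepted on read).
#'
#' @param path JSON file path.
#' @param trait_names trait universe used for validation.
#' @return named list of `modularity_model` objects.
#' @export
read_models <- function(path, trait_names = paste0("d", 1:21)) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(raw$name)) raw <- list(raw)
  models <- lapply(raw, function(x) {
    if (is.null(x$name) || is.null(x$modules)) {
      stop(path, ": each model needs 'name' and 'modules'")
    }
    modularity_model(x$name,
                     lapply(x$modules, function(v) unlist(v, use.names = FALSE)),
                     trait_names = trait_names)
  })
  stats::setNames(models, vapply(models, `[[`, character(1), "name"))
}

#' @rdname read_models
#' @param models list of `modularity_model` objects to write.
#' @export
write_models <- function(models, path) {
  if (inherits(models, "modularity_model")) models <- list(models)
  out <- lapply(models, function(m) {
    list(name = m$name, modules = m$modules, background = m$background)
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a locality-level climate table
#'
#' Climate CSV layout: `locality,species,BIO1,...,BIO19`. BIO3 and BIO7
#' (thermal-amplitude combinations of other variables) are dropped on load
#' with a message.
#'
#' @param path CSV file path.
#' @param drop variables removed on load (default BIO3, BIO7).
#' @return data.frame with `locality`, `species` and the retained variables.
#' @export
read_climate <- function(path, drop = c("BIO3", "BIO7")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("locality", "species") %in% names(df))) {
    stop(path, " needs 'locality' and 'species' columns")
  }
  found <- intersect(drop, names(df))
  if (length(found) > 0) {
    message("dropping collinear climate variables: ",
            paste(found, collapse = ", "))
    df <- df[setdiff(names(df), found)]
  }
  df
}

#' Write / read a dissimilarity matrix as CSV plus JSON sidecar
#'
#' @param D a `dist_matrix`.
#' @param path file stem (no extension).
#' @export
write_dist_matrix <- function(D, path) {
  stopifnot(inherits(D, "dist_matrix"))
  utils::write.csv(as.data.frame(D$values), paste0(path, ".csv"),
                   quote = FALSE)
  jsonlite::write_json(list(method = D$method, seed = D$seed),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  M <- as.matrix(utils::read.csv(paste0(path, ".csv"), row.names = 1,
                                 check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(labels = rownames(M), values = M, method = meta$method,
                 seed = if (is.null(meta$seed)) NA_integer_ else meta$seed),
            class = "dist_matrix")
}

#' Read a YAML run configuration
#'
#' Run configurations gather input paths, the matrix kind
#' (`with_size | no_isometric | no_allometric`), bootstrap sizes, seeds and
#' an output directory for the analysis scripts. Referenced files must
#' exist at load time.
#'
#' @param path YAML file path.
#' @return named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in intersect(c("traits", "tree", "climate", "models"), names(cfg))) {
    if (!file.exists(cfg[[key]])) {
      stop("run config references a missing file: ", key, " = ", cfg[[key]])
    }
  }
  if (!is.null(cfg$kind) &&
      !cfg$kind %in% c("with_size", "no_isometric", "no_allometric")) {
    stop("kind must be with_size, no_isometric or no_allometric")
  }
  structure(cfg, class = "run_config")
}

#' Write a variation-partitioning result
#'
#' Writes the fractions and tests both as JSON (`<path>.json`) and as a
#' long-format CSV (`<path>.csv`: fraction, adjusted R2, F, p).
#'
#' @param vp a `varpart_result`.
#' @param path file stem.
#' @export
write_varpart <- function(vp, path) {
  stopifnot(inherits(vp, "varpart_result"))
  tab <- data.frame(
    fraction = c("X1", "X2", "X1|X2", "X2|X1", "shared", "residual"),
    adj_r2 = c(vp$r2adj_X1, vp$r2adj_X2, vp$frac_a, vp$frac_c, vp$frac_b,
               vp$residual),
    F = c(vp$tests$F, NA),
    p = c(vp$tests$p, NA))
  utils::write.csv(tab, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(r2adj_X1 = vp$r2adj_X1, r2adj_X2 = vp$r2adj_X2,
         r2adj_full = vp$r2adj_full, frac_a = vp$frac_a,
         frac_b = vp$frac_b, frac_c = vp$frac_c, residual = vp$residual,
         n = vp$n, n_perm = vp$n_perm, seed = vp$seed,
         tests = vp$tests),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a clade dataset to a directory
#'
#' Writes the trait table, tree (newick), locality climate table and the
#' generating parameters (`truth.json`) in the formats the pipeline reads.
#'
#' @param dataset a `clade_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_clade <- function(dataset, dir) {
  stopifnot(inherits(dataset, "clade_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trait_table(dataset$traits, file.path(dir, "traits.csv"))
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(dataset$climate, file.path(dir, "climate.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- dataset$truth$config
  truth <- list(
    config = cfg[setdiff(names(cfg), "true_model")],
    true_model = list(name = cfg$true_model$name,
                      modules = cfg$true_model$modules,
                      background = cfg$true_model$background),
    climate_scores = as.list(dataset$truth$climate_scores),
    module_scale = dataset$truth$module_scale)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
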