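# Validated CSV readers/writers for the survey tables and result tables.
#
# CSV dialect: UTF-8, comma separator, "." decimal, header row required,
# missing values as empty strings.

.required_cols <- list(
  detections = c("site_id", "species_id", "abundance_code"),
  sites = c("site_id", "region", "n_dep", "s_dep", "precip_mm",
            "tmax_aug_c", "tmin_dec_c", "continentality_c", "cmd_mm"),
  species = c("species_id", "genus", "growth_form", "photobiont",
              "functional_group", "n_rating_east", "n_rating_west",
              "s_rating_east", "s_rating_west")
)

.read_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  fileEncoding = "UTF-8")
}

#' Read and validate a survey dataset from CSV files
#'
#' Loads the detections, sites and species tables, checks the schema and
#' referential integrity, and reports *all* validation failures together
#' (with row numbers) rather than stopping at the first. No partially
#' loaded dataset is ever returned.
#'
#' @param paths named list/vector with elements `detections`, `sites`,
#'   `species` (CSV file paths).
#' @return list of class `"lichen_dataset"` with the three tables and
#'   provenance metadata (`source`, `units`, `date`).
#' @export
read_dataset <- function(paths) {
  need <- c("detections", "sites", "species")
  if (!all(need %in% names(paths))) {
    stop("paths must name detections, sites and species files")
  }
  missing <- !file.exists(unlist(paths[need]))
  if (any(missing)) {
    stop("file(s) not found: ",
         paste(unlist(paths[need])[missing], collapse = ", "))
  }
  tabs <- lapply(paths[need], .read_csv)
  problems <- character()
  for (nm in need) {
    absent <- setdiff(.required_cols[[nm]], names(tabs[[nm]]))
    if (length(absent)) {
      problems <- c(problems, sprintf("%s: missing column(s) %s", nm,
                                      paste(absent, collapse = ", ")))
    }
  }
  if (!length(problems)) {
    det <- tabs$detections
    sites <- tabs$sites
    spp <- tabs$species
    bad <- which(!det$abundance_code %in% 1:4)
    if (length(bad)) {
      problems <- c(problems,
                    sprintf("detections: abundance_code outside 1-4 at row(s) %s",
                            paste(utils::head(bad, 20), collapse = ", ")))
    }
    orphan_site <- which(!det$site_id %in% sites$site_id)
    if (length(orphan_site)) {
      problems <- c(problems,
                    sprintf("detections: unknown site_id at row(s) %s",
                            paste(utils::head(orphan_site, 20),
                                  collapse = ", ")))
    }
    orphan_sp <- which(!det$species_id %in% spp$species_id)
    if (length(orphan_sp)) {
      problems <- c(problems,
                    sprintf("detections: unknown species_id at row(s) %s",
                            paste(utils::head(orphan_sp, 20),
                                  collapse = ", ")))
    }
    for (col in c("n_dep", "s_dep")) {
      v <- suppressWarnings(as.numeric(sites[[col]]))
      nn <- which(is.na(v) & !is.na(sites[[col]]))
      if (length(nn)) {
        problems <- c(problems,
                      sprintf("sites: non-numeric %s at row(s) %s", col,
                              paste(utils::head(nn, 20), collapse = ", ")))
      }
      neg <- which(v < 0)
      if (length(neg)) {
        problems <- c(problems,
                      sprintf("sites: negative %s at row(s) %s", col,
                              paste(utils::head(neg, 20), collapse = ", ")))
      }
    }
    bad_rg <- which(!sites$region %in% c("East", "West"))
    if (length(bad_rg)) {
      problems <- c(problems,
                    sprintf("sites: region must be East or West at row(s) %s",
                            paste(utils::head(bad_rg, 20), collapse = ", ")))
    }
    dup <- which(duplicated(det[c("site_id", "species_id")]))
    if (length(dup)) {
      problems <- c(problems,
                    sprintf("detections: duplicate (site, species) at row(s) %s",
                            paste(utils::head(dup, 20), collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("dataset validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  }
  out <- list(detections = tabs$detections, sites = tabs$sites,
              species = tabs$species,
              provenance = list(source = unname(unlist(paths[need])),
                                units = "kg ha-1 yr-1",
                                date = format(Sys.Date())))
  class(out) <- "lichen_dataset"
  out
}

#' Write the three survey tables of a dataset as CSV
#'
#' @param dataset a `"lichen_dataset"` or `"synthetic_dataset"`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(detections = file.path(dir, "detections.csv"),
             sites = file.path(dir, "sites.csv"),
             species = file.path(dir, "species.csv"))
  for (nm in names(paths)) {
    utils::write.csv(dataset[[nm]], paths[nm], row.names = FALSE,
                     na = "")
  }
  if (!is.null(dataset$true_model)) {
    jsonlite::write_json(dataset$true_model,
                         file.path(dir, "true_model.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(paths)
}

#' Write result tables and objects with a checksummed manifest
#'
#' Data frames are written as CSV, other objects as JSON, under
#' deterministic file names; re-writing identical results yields
#' byte-identical files. Empty (`NULL` or zero-row) sections are omitted
#' and noted in the manifest. The manifest records an md5 checksum per
#' file.
#'
#' @param results named list of data.frames and/or lists.
#' @param dir output directory.
#' @return the manifest (also written to `manifest.json`), invisibly.
#' @export
write_results <- function(results, dir) {
  if (!length(results) || is.null(names(results))) {
    stop("results must be a nonempty named list")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  omitted <- character()
  for (nm in sort(names(results))) {
    obj <- results[[nm]]
    empty <- is.null(obj) ||
      (is.data.frame(obj) && nrow(obj) == 0) ||
      (is.list(obj) && !length(obj))
    if (empty) {
      omitted <- c(omitted, nm)
      next
    }
    if (is.data.frame(obj)) {
      path <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(obj, path, row.names = FALSE, na = "")
    } else {
      path <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    }
    files[[nm]] <- list(file = basename(path),
                        md5 = unname(tools::md5sum(path)))
  }
  manifest <- list(files = files, omitted = as.list(omitted))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Verify a result manifest's checksums
#'
#' @param dir directory containing `manifest.json` and the result files.
#' @return logical: do all checksums match?
#' @export
verify_manifest <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  all(vapply(manifest$files, function(f) {
    identical(unname(tools::md5sum(file.path(dir, f$file))),
              f$md5)
  }, logical(1)))
}
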