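#' Write a lesion report to CSV and JSON
#'
#' Emits `<path>.csv` (per-lesion rows sorted by cap area descending, with a
#' `#`-prefixed footer carrying the totals) and `<path>.json` (the complete
#' report, full numeric precision, including the analysis parameters).
#' [read_report()] restores the report from the JSON, reproducing every
#' numeric field exactly; the label grid is not serialised here (see
#' [write_labels()]).
#'
#' @param report A `lesion_report` from [detect_lesions()].
#' @param path Output path without extension (or with `.csv`/`.json`, which
#'   is stripped).
#' @return Invisibly, the two file paths written.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "lesion_report"))
  base <- sub("\\.(csv|json)$", "", path)
  dir <- dirname(base)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  csv <- paste0(base, ".csv"); json <- paste0(base, ".json")

  con <- file(csv, open = "wt")
  on.exit(close(con), add = TRUE)
  utils::write.csv(fmt_df(report$lesions), con, row.names = FALSE, quote = FALSE)
  writeLines(c(
    sprintf("# bone_surface_area_um2,%s", fmt_num(report$bone_surface_area_um2)),
    sprintf("# bone_surface_area_raw_um2,%s", fmt_num(report$bone_surface_area_raw_um2)),
    sprintf("# total_lesion_area_um2,%s", fmt_num(report$total_lesion_area_um2)),
    sprintf("# lesion_percent,%s", fmt_num(report$lesion_percent))), con)

  payload <- report[c("lesions", "bone_surface_area_um2",
                      "bone_surface_area_raw_um2", "total_lesion_area_um2",
                      "lesion_percent", "voxel_size_um", "params")]
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(c(csv = csv, json = json))
}

fmt_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

fmt_df <- function(df) {
  for (cl in names(df)) if (is.double(df[[cl]])) df[[cl]] <- fmt_num(df[[cl]])
  df
}

#' Read a lesion report written by [write_report()]
#'
#' @param path The report base path or the `.json` file itself.
#' @return A `lesion_report` (without the label grid).
#' @export
read_report <- function(path) {
  json <- if (grepl("\\.json$", path)) path else paste0(sub("\\.csv$", "", path), ".json")
  if (!file.exists(json)) stop("report file does not exist: ", json)
  p <- jsonlite::read_json(json, simplifyVector = TRUE)
  df <- as.data.frame(p$lesions)
  if (length(df) == 0L || nrow(df) == 0L) df <- empty_lesion_df()
  df$id <- as.integer(df$id)
  df$fill_vox <- as.integer(df$fill_vox)
  for (cl in c("cap_area_um2", "exposed_faces_um2", "centroid_z_um",
               "centroid_y_um", "centroid_x_um"))
    df[[cl]] <- as.numeric(df[[cl]])
  structure(list(lesions = df,
                 bone_surface_area_um2 = as.numeric(p$bone_surface_area_um2),
                 bone_surface_area_raw_um2 = as.numeric(p$bone_surface_area_raw_um2),
                 total_lesion_area_um2 = as.numeric(p$total_lesion_area_um2),
                 lesion_percent = as.numeric(p$lesion_percent),
                 labels = NULL,
                 voxel_size_um = p$voxel_size_um,
                 params = p$params),
            class = "lesion_report")
}
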