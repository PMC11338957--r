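#' Read a fold-change time-course table
#'
#' Reads a delimited table of total and nascent mRNA signal versus time
#' and normalizes both series by their value at the reference time
#' (t = 0), the convention of the depletion time-course datasets. Rows
#' with missing values are dropped with a message.
#'
#' @param path CSV file path.
#' @param columns Named character vector mapping the canonical names
#'   `time`, `total`, `nascent` to the file's column names; default
#'   `c(time = "time_min", total = "total_fold", nascent = "nascent_fold")`.
#' @param ref_time Reference time for normalization (default 0).
#' @param nearest_ref Allow the nearest time point to stand in for a
#'   missing exact reference row? Off by default; turning it on flags the
#'   dataset via the `ref_time_used` attribute.
#' @return A tibble `time`, `total_fold`, `nascent_fold` with both folds
#'   equal to 1 at the reference time.
#' @export
read_timecourse_table <- function(path,
                                  columns = c(time = "time_min",
                                              total = "total_fold",
                                              nascent = "nascent_fold"),
                                  ref_time = 0, nearest_ref = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(unname(columns), names(raw))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  ds <- tibble::tibble(time = raw[[columns[["time"]]]],
                       total = raw[[columns[["total"]]]],
                       nascent = raw[[columns[["nascent"]]]])
  n0 <- nrow(ds)
  ds <- ds[stats::complete.cases(ds), ]
  if (nrow(ds) < n0) {
    message("dropped ", n0 - nrow(ds), " row(s) with missing values")
  }
  if (nrow(ds) == 0) stop("no complete rows in ", path, call. = FALSE)
  i0 <- which(ds$time == ref_time)
  if (length(i0) == 0) {
    if (!nearest_ref) {
      stop("no row at reference time ", ref_time,
           " (set nearest_ref = TRUE to use the closest point)",
           call. = FALSE)
    }
    i0 <- which.min(abs(ds$time - ref_time))
  }
  i0 <- i0[1]
  out <- tibble::tibble(time = ds$time,
                        total_fold = ds$total / ds$total[i0],
                        nascent_fold = ds$nascent / ds$nascent[i0])
  attr(out, "ref_time_used") <- ds$time[i0]
  out
}

#' Read a perturbation-screen table
#'
#' Reads a per-sample screen table (one row per sample, columns for the
#' target-gene label, nuclear and cytoplasmic concentration signals, the
#' production signal, and a scrambled-control flag), averages signals per
#' gene, and normalizes by the scrambled-control means to obtain fold
#' changes.
#'
#' @param path CSV file path.
#' @param columns Named character vector mapping `gene`, `nuclear`,
#'   `cytoplasmic`, `production`, `scrambled` to the file's column names.
#' @return A list: `table` (the per-sample tibble) and `folds` (per-gene
#'   tibble with `gene`, `nuclear_fold`, `cytoplasmic_fold`,
#'   `production_fold`).
#' @export
read_screen_table <- function(path,
                              columns = c(gene = "gene",
                                          nuclear = "nuclear_signal",
                                          cytoplasmic = "cytoplasmic_signal",
                                          production = "production_signal",
                                          scrambled = "scrambled")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(unname(columns), names(raw))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tab <- tibble::tibble(gene = raw[[columns[["gene"]]]],
                        nuclear = raw[[columns[["nuclear"]]]],
                        cytoplasmic = raw[[columns[["cytoplasmic"]]]],
                        production = raw[[columns[["production"]]]],
                        scrambled = as.logical(raw[[columns[["scrambled"]]]]))
  if (!any(tab$scrambled)) {
    stop("no scrambled-control records; cannot normalize", call. = FALSE)
  }
  ctrl <- dplyr::summarise(dplyr::filter(tab, .data$scrambled),
                           nuclear = mean(.data$nuclear),
                           cytoplasmic = mean(.data$cytoplasmic),
                           production = mean(.data$production))
  folds <- tab |>
    dplyr::filter(!.data$scrambled) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(nuclear_fold = mean(.data$nuclear) / ctrl$nuclear,
                     cytoplasmic_fold = mean(.data$cytoplasmic) /
                       ctrl$cytoplasmic,
                     production_fold = mean(.data$production) /
                       ctrl$production,
                     .groups = "drop")
  list(table = tab, folds = folds)
}

#' Load a parameter configuration
#'
#' Flat JSON with parameter names exactly as in [rs_params()]; unknown
#' keys are rejected, missing keys fall back to the basic set (with a
#' message). An optional `"variant"` block selects a model variant by
#' name and supplies its extras.
#'
#' @param path JSON file path.
#' @return An `rs_params` object, or an `rs_variant` when a `"variant"`
#'   block is present.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  variant_block <- cfg[["variant"]]
  cfg[["variant"]] <- NULL
  unknown <- setdiff(names(cfg), rs_param_names())
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad <- names(cfg)[!vapply(cfg, function(v)
    is.numeric(v) && length(v) == 1, logical(1))]
  if (length(bad) > 0) {
    stop("configuration key(s) not numeric scalars: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(rs_param_names(), names(cfg))
  if (length(missing) > 0) {
    message("filling ", length(missing),
            " missing parameter(s) from the basic set")
  }
  p <- do.call(rs_params, cfg)
  if (is.null(variant_block)) return(p)
  if (is.null(variant_block$kind)) stop("variant block must name a 'kind'")
  extras <- variant_block[setdiff(names(variant_block), "kind")]
  do.call(rs_variant, c(list(kind = variant_block$kind, params = p), extras))
}

#' Write a time-course dataset / screen table as CSV
#'
#' Canonical delimited formats that round-trip through
#' [read_timecourse_table()] and [read_screen_table()].
#'
#' @param ds Tibble with `time`, `total_fold`, `nascent_fold`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_table <- function(ds, path) {
  out <- tibble::tibble(time_min = ds$time, total_fold = ds$total_fold,
                        nascent_fold = ds$nascent_fold)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_timecourse_table
#' @param tab Per-sample screen tibble with columns `gene`, `nuclear`,
#'   `cytoplasmic`, `production`, `scrambled`.
#' @export
write_screen_table <- function(tab, path) {
  out <- tibble::tibble(gene = tab$gene, nuclear_signal = tab$nuclear,
                        cytoplasmic_signal = tab$cytoplasmic,
                        production_signal = tab$production,
                        scrambled = tab$scrambled)
  readr::write_csv(out, path)
  invisible(path)
}
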