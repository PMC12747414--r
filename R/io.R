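# CSV readers/writers and JSON report plumbing. Survival CSVs carry either
# `n,assayed,functional` counts or `n,proportion`; ddG CSVs carry
# `protein,ddg[,position,wt,mut]`. Comment lines start with `#`.

#' Read a mutational-survival CSV
#'
#' Accepts either schema: `n,assayed,functional` (counts; the proportion
#' is derived) or `n,proportion`. Lines starting with `#` are comments.
#' Malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @return A [survival_curve()].
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  names(dat) <- tolower(names(dat))
  has_counts <- all(c("n", "assayed", "functional") %in% names(dat))
  has_prop <- all(c("n", "proportion") %in% names(dat))
  if (!has_counts && !has_prop)
    stop("survival CSV needs header n,assayed,functional or n,proportion (got: ",
         paste(names(dat), collapse = ","), ")")
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop("invalid survival CSV rows (", what, "): data row(s) ",
           paste(rows, collapse = ", "))
  }
  bad(!is.finite(dat$n) | dat$n < 0 | dat$n != floor(dat$n), "n must be a non-negative integer")
  if (has_counts) {
    bad(!is.finite(dat$assayed) | dat$assayed <= 0, "assayed must be positive")
    bad(!is.finite(dat$functional) | dat$functional < 0, "functional must be non-negative")
    bad(dat$functional > dat$assayed, "functional exceeds assayed")
    survival_curve(n = dat$n, assayed = dat$assayed, functional = dat$functional)
  } else {
    bad(!is.finite(dat$proportion) | dat$proportion < 0 | dat$proportion > 1,
        "proportion outside [0, 1]")
    survival_curve(n = dat$n, prop = dat$proportion)
  }
}

#' Write a survival curve as CSV
#'
#' Writes the counts schema when counts are present, otherwise the
#' proportion schema; the output is accepted by [read_survival_csv()].
#'
#' @param curve A [survival_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  if (!is.null(curve$assayed)) {
    out <- data.frame(n = curve$n, assayed = curve$assayed,
                      functional = curve$functional)
  } else {
    out <- data.frame(n = curve$n, proportion = curve$prop)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-mutation ddG CSV
#'
#' Expects header `protein,ddg` with optional `position,wt,mut` columns;
#' ddG in kcal/mol, positive = destabilizing. Comment lines start with
#' `#`.
#'
#' @param path File path.
#' @return A [ddg_table()].
#' @export
read_ddg_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  names(dat) <- tolower(names(dat))
  if (!all(c("protein", "ddg") %in% names(dat)))
    stop("ddG CSV needs header protein,ddg (got: ",
         paste(names(dat), collapse = ","), ")")
  rows <- which(!is.finite(dat$ddg))
  if (length(rows))
    stop("invalid ddG CSV rows (non-finite ddg): data row(s) ",
         paste(rows, collapse = ", "))
  ddg_table(protein = dat$protein, ddg = dat$ddg,
            position = dat$position, wt = dat$wt, mut = dat$mut)
}

#' @rdname read_ddg_csv
#' @param table A [ddg_table()].
#' @param path Output path.
#' @export
write_ddg_csv <- function(table, path) {
  stopifnot(inherits(table, "ddg_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' JSON report of a hyper-exponential fit
#'
#' Emits `{alpha, beta, sigma_alpha, sigma_beta, r2_hyper, r2_exp,
#' epistatic}` as JSON.
#'
#' @param fit A [hyperexp_fit()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
write_fit_json <- function(fit, path = NULL) {
  fit <- as_hyperexp_fit(fit)
  x <- fit[c("alpha", "beta", "sigma_alpha", "sigma_beta",
             "r2_hyper", "r2_exp", "epistatic")]
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write and read a pipeline report bundle
#'
#' `write_report()` serialises a [run_epistatic_pipeline()] result as a
#' deterministic JSON report (raw log10 values, formatted exponents,
#' convention tag, all inputs echoed, package version) plus a CSV sidecar
#' with the functional-density / FSH table. Two runs with the same config
#' produce byte-identical files. `read_report()` parses the JSON back.
#'
#' @param run A `prism_run` from [run_epistatic_pipeline()].
#' @param path Output path for the JSON report; the sidecar gets the same
#'   path with extension `.fsh.csv`.
#' @return `path`, invisibly (for `write_report`); a named list (for
#'   `read_report`).
#' @export
write_report <- function(run, path) {
  stopifnot(inherits(run, "prism_run"))
  rep <- run$report
  payload <- list(
    tool = "prismr",
    version = as.character(utils::packageVersion("prismr")),
    inputs = run$inputs,
    fit = list(alpha = run$fit$alpha, beta = run$fit$beta,
               sigma_alpha = run$fit$sigma_alpha,
               sigma_beta = run$fit$sigma_beta,
               r2_hyper = run$fit$r2_hyper, r2_exp = run$fit$r2_exp,
               epistatic = run$fit$epistatic),
    target = run$target,
    discovery = run$discovery,
    rarity = list(log10_pt = rep$log10_pt, log10_pubt = rep$log10_pubt,
                  log10_pub = rep$log10_pub, exponents = rep$exponents,
                  convention = rep$convention)
  )
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              na = "null", pretty = TRUE), path)
  fsh <- fsh_map_data(run$density)
  utils::write.csv(fsh, sub("\\.json$", "", path) |> paste0(".fsh.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
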