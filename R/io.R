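#' Read manifold points from CSV/TSV
#'
#' One point per row, `D + 1` numeric columns (header optional; separator
#' inferred from the extension or content). Curvature and dimension come from
#' `form`, never from the file. Rows violating the manifold constraint are
#' rejected with their indices, or renormalized under `repair = TRUE`.
#'
#' @param path File path.
#' @param form A [space_form()].
#' @param repair Renormalize invalid rows (with a warning) instead of failing.
#' @param tol Constraint tolerance.
#' @return Matrix of validated points, one per row.
#' @export
read_points <- function(path, form, repair = FALSE, tol = 1e-6) {
  x <- read_numeric_table(path)
  if (ncol(x) != form$dim + 1L)
    stop("expected ", form$dim + 1L, " columns, found ", ncol(x))
  ok <- sf_on_manifold(form, x, tol)
  if (!all(ok)) {
    if (repair) {
      warning("renormalized ", sum(!ok), " row(s) to the manifold")
      x[!ok, ] <- rbind(sf_normalize(form, x[!ok, , drop = FALSE]))
    } else {
      stop("rows violate the ", form$type, " constraint: ",
           paste(utils::head(which(!ok), 10L), collapse = ", "))
    }
  }
  x
}

read_numeric_table <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  has_header <- any(is.na(suppressWarnings(
    as.numeric(strsplit(first, sep, fixed = TRUE)[[1]]))))
  d <- utils::read.table(path, sep = sep, header = has_header,
                         comment.char = "", check.names = FALSE)
  num <- vapply(d, is.numeric, logical(1))
  if (!all(num)) {
    if (!num[1L] && all(num[-1L])) d <- d[, -1L, drop = FALSE]  # id column
    else stop("non-numeric column(s) in ", path)
  }
  as.matrix(d)
}

#' Write points to CSV
#'
#' @param x Point matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_points <- function(x, path) {
  utils::write.table(rbind(x), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a labeled distance matrix from CSV
#'
#' Square numeric matrix, optionally with a label header row/column.
#'
#' @param path File path.
#' @return List with `labels` (or `NULL`) and `matrix`.
#' @export
read_distance_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  labels <- NULL
  if (!is.numeric(d[[1L]])) { labels <- as.character(d[[1L]]); d <- d[, -1L] }
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  dimnames(m) <- NULL
  list(labels = labels, matrix = (m + t(m)) / 2)
}

#' Write a structured report as JSON
#'
#' Adds a schema version, the resolved seed/config when given, and the package
#' version, so every output file is self-describing.
#'
#' @param report Named list (any module's report).
#' @param path Output path (`.json`).
#' @param config Optional config echo.
#' @param seed Optional seed echo.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, config = NULL, seed = NULL) {
  payload <- c(list(schema = "spaceform/report/1",
                    package_version = as.character(utils::packageVersion("spaceform"))),
               if (!is.null(seed)) list(seed = seed),
               if (!is.null(config)) list(config = config),
               report)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' Serialize / deserialize a PCA fit as JSON
#'
#' @param fit An `"sfpca"` object.
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` the fit.
#' @export
write_model <- function(fit, path) {
  obj <- list(schema = "spaceform/model/1", method = fit$method,
              curvature = fit$form$curvature, dim = fit$form$dim, K = fit$K,
              base = fit$base, tangent_basis = fit$tangent_basis,
              spectrum = fit$spectrum, signs = fit$signs, meta = fit$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  form <- space_form(obj$curvature, obj$dim)
  new_sfpca(form, as.numeric(obj$base), rbind(obj$tangent_basis),
            as.numeric(obj$spectrum),
            signs = if (is.null(obj$signs)) NULL else as.numeric(obj$signs),
            K = obj$K, meta = as.list(obj$meta), method = obj$method)
}
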