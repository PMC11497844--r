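#' Read an expression-model weight table
#'
#' Loads a PredictDB-style table of per-gene cis-variant weights. The TSV
#' dialect is canonical: a header `gene variant_id ref_allele effect_allele
#' weight` followed by one row per (gene, variant) pair. The SQLite dialect
#' mirrors the PredictDB schema: a `weights` table with columns `gene`,
#' `rsid`, `varID`, `ref_allele`, `eff_allele`, `weight` plus an `extra`
#' table of per-gene metadata.
#'
#' Gene order is first-appearance order in the file; variant order within a
#' gene is file order. Matching between models, frequency tables and dosage
#' files is exact string equality on `variant_id` (the
#' `chr_pos_ref_alt_build` convention); no allele flipping or liftover is
#' attempted.
#'
#' @param path Path to the model file.
#' @param dialect `"tsv"` (default) or `"sqlite"`.
#' @param tissue Optional tissue label attached to the model; defaults to
#'   the file name without extension.
#' @return A tibble of class `expr_model` with columns `gene`, `variant_id`,
#'   `ref_allele`, `effect_allele`, `weight` and a `tissue` attribute.
#' @examples
#' m <- synth_models(synth_config(n_tissues = 1, n_genes = 3, seed = 1))[[1]]
#' f <- tempfile(fileext = ".tsv")
#' write_model(m, f)
#' identical(as.data.frame(read_model(f)), as.data.frame(m))
#' @seealso [write_model()], [predict_expression()]
#' @export
read_model <- function(path, dialect = c("tsv", "sqlite"), tissue = NULL) {
  dialect <- arg_match(dialect)
  if (!file.exists(path)) {
    abort(sprintf("Model file not found: %s", path))
  }
  if (is.null(tissue)) {
    tissue <- sub("\\.[^.]*$", "", basename(path))
  }
  if (dialect == "sqlite") {
    return(read_model_sqlite(path, tissue))
  }
  header <- c("gene", "variant_id", "ref_allele", "effect_allele", "weight")
  raw <- readr::read_tsv(path,
    col_types = readr::cols(
      gene = readr::col_character(),
      variant_id = readr::col_character(),
      ref_allele = readr::col_character(),
      effect_allele = readr::col_character(),
      weight = readr::col_character()
    ),
    progress = FALSE
  )
  if (!identical(names(raw), header)) {
    abort(sprintf(
      "Model header must be '%s'; got '%s'.",
      paste(header, collapse = " "), paste(names(raw), collapse = " ")
    ))
  }
  weight <- suppressWarnings(as.numeric(raw$weight))
  bad <- which(is.na(weight) | !is.finite(weight))
  if (length(bad)) {
    # +1 for the header line
    abort(sprintf(
      "Missing or non-finite weight on line %s of %s.",
      paste(bad + 1L, collapse = ", "), path
    ))
  }
  raw$weight <- weight
  new_expr_model(raw, tissue)
}

read_model_sqlite <- function(path, tissue) {
  check_sqlite_available()
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  tabs <- DBI::dbListTables(con)
  if (!"weights" %in% tabs) {
    abort(sprintf("SQLite model %s has no 'weights' table.", path))
  }
  w <- as_tibble(DBI::dbReadTable(con, "weights"))
  out <- tibble(
    gene = as.character(w$gene),
    variant_id = as.character(w$varID),
    ref_allele = as.character(w$ref_allele),
    effect_allele = as.character(w$eff_allele),
    weight = as.numeric(w$weight)
  )
  if (any(!is.finite(out$weight))) {
    abort(sprintf("Missing or non-finite weight in SQLite model %s.", path))
  }
  new_expr_model(out, tissue)
}

new_expr_model <- function(tbl, tissue) {
  if (nrow(tbl) == 0) {
    abort("Expression model has no weight rows.")
  }
  if (any(!nzchar(tbl$variant_id)) || anyNA(tbl$variant_id)) {
    abort("Expression model has empty variant ids.")
  }
  dup <- duplicated(tbl[, c("gene", "variant_id")])
  if (any(dup)) {
    ex <- tbl[dup, ]
    abort(sprintf(
      "Duplicate (gene, variant) pairs are not allowed; first duplicate: (%s, %s).",
      ex$gene[1], ex$variant_id[1]
    ))
  }
  out <- as_tibble(tbl)
  attr(out, "tissue") <- tissue
  class(out) <- c("expr_model", class(out))
  out
}

check_sqlite_available <- function() {
  if (!requireNamespace("RSQLite", quietly = TRUE) ||
      !requireNamespace("DBI", quietly = TRUE)) {
    abort("The sqlite dialect needs the RSQLite and DBI packages.")
  }
}

#' Write an expression-model weight table
#'
#' @param model An `expr_model` tibble (see [read_model()]).
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"sqlite"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("tsv", "sqlite")) {
  dialect <- arg_match(dialect)
  model <- validate_model(model)
  if (dialect == "tsv") {
    readr::write_tsv(as_tibble(as.data.frame(model)), path, progress = FALSE)
  } else {
    check_sqlite_available()
    if (file.exists(path)) file.remove(path)
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    DBI::dbWriteTable(con, "weights", data.frame(
      gene = model$gene,
      rsid = model$variant_id,
      varID = model$variant_id,
      ref_allele = model$ref_allele,
      eff_allele = model$effect_allele,
      weight = model$weight,
      stringsAsFactors = FALSE
    ))
    extra <- as.data.frame(count(as_tibble(as.data.frame(model)), .data$gene, name = "n.snps.in.model"))
    DBI::dbWriteTable(con, "extra", extra)
  }
  invisible(path)
}

validate_model <- function(model) {
  stop_if_not_df(model, "model")
  need <- c("gene", "variant_id", "ref_allele", "effect_allele", "weight")
  if (!all(need %in% names(model))) {
    abort(sprintf("Model must have columns: %s.", paste(need, collapse = ", ")))
  }
  if (nrow(model) == 0) abort("Expression model has no weight rows.")
  if (any(!is.finite(model$weight))) abort("Model weights must be finite.")
  if (anyDuplicated(model[, c("gene", "variant_id")])) {
    abort("Duplicate (gene, variant) pairs are not allowed.")
  }
  model
}

# ---- subject-major matrix files (dosage and prediction) ---------------------

parse_subject_file <- function(path, kind, lo = -Inf, hi = Inf,
                                require_finite = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: %s", kind, path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) {
    abort(sprintf("%s file %s is empty.", kind, path))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  header <- fields[[1]]
  if (length(header) < 3 || !identical(header[1:2], c("FID", "IID"))) {
    abort(sprintf("%s header must be 'FID IID <ids...>'.", kind))
  }
  body <- fields[-1]
  widths <- lengths(body)
  ragged <- which(widths != length(header))
  if (length(ragged)) {
    abort(sprintf(
      "Ragged %s file: row %s has %d fields, expected %d.",
      kind, ragged[1], widths[ragged[1]], length(header)
    ))
  }
  ids <- header[-(1:2)]
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate column ids in %s file.", kind))
  }
  fid <- vapply(body, `[[`, character(1), 1)
  iid <- vapply(body, `[[`, character(1), 2)
  raw <- unlist(lapply(body, `[`, -(1:2)), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(raw))
  if (require_finite && any(!is.finite(vals))) {
    bad <- which(!is.finite(vals))[1]
    row <- (bad - 1) %/% length(ids) + 1
    abort(sprintf("Non-numeric value in %s file at row %d.", kind, row))
  }
  if (any(vals < lo | vals > hi, na.rm = TRUE)) {
    bad <- which(vals < lo | vals > hi)[1]
    row <- (bad - 1) %/% length(ids) + 1
    abort(sprintf(
      "%s value %.6g at row %d is outside [%g, %g].",
      kind, vals[bad], row, lo, hi
    ))
  }
  m <- matrix(vals, nrow = length(body), byrow = TRUE,
              dimnames = list(NULL, ids))
  out <- dplyr::bind_cols(tibble(FID = fid, IID = iid), as_tibble(m))
  out
}

write_subject_file <- function(x, path, arg) {
  check_subject_table(x, arg)
  readr::write_tsv(as_tibble(as.data.frame(x)), path, progress = FALSE)
  invisible(path)
}

#' Read a dosage matrix
#'
#' Reads a subjects-by-variants allele-count matrix in the PrediXcan dosage
#' convention: header `FID IID` followed by variant ids, one whitespace- or
#' tab-delimited row per subject. Every dosage must lie in \[0, 2\] (copies
#' of the model's effect allele).
#'
#' @param path Path to the dosage file.
#' @return A tibble with character columns `FID`, `IID` and one numeric
#'   column per variant.
#' @export
read_dosage <- function(path) {
  parse_subject_file(path, "dosage", lo = 0, hi = 2)
}

#' Write a dosage matrix
#'
#' @param dosages A dosage tibble (`FID`, `IID`, variant columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage <- function(dosages, path) {
  vals <- subject_values(check_subject_table(dosages, "dosages"))
  if (any(vals < 0 | vals > 2)) {
    abort("Dosages must lie in [0, 2].")
  }
  write_subject_file(dosages, path, "dosages")
}

#' Read a predicted-expression matrix
#'
#' Reads PrediXcan-style predicted expression: header `FID IID` followed by
#' gene ids, one row per subject.
#'
#' @param path Path to the prediction file.
#' @return A tibble with character columns `FID`, `IID` and one numeric
#'   column per gene.
#' @export
read_prediction <- function(path) {
  parse_subject_file(path, "prediction")
}

#' Write a predicted-expression matrix
#'
#' @param predictions A prediction tibble (`FID`, `IID`, gene columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(predictions, path) {
  write_subject_file(predictions, path, "predictions")
}
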