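#' Column-name schema for cohort tables
#'
#' Maps the semantic fields of a patient record to the column names of a
#' delimited cohort file. The default matches the canonical layout
#' `patient_id,sex,age,bmi,glu_0,glu_30,glu_60,glu_120,ins_0,ins_30,ins_60,
#' ins_120,uric_acid,hba1c,cohort_id,<comorbidity>...`. This layout is an
#' artifact of this package (source studies rarely publish their table
#' layouts); any export can be adapted by renaming entries here.
#'
#' Units are fixed by the schema and never converted on input: glucose in
#' mmol/L, insulin in mU/L, uric acid in \eqn{\mu}mol/L.
#'
#' @param comorbidities Character vector of comorbidity column names, or
#'   `NULL` to treat every unmapped column as a comorbidity flag.
#' @return A named list of column mappings, class `cohort_schema`.
#' @export
cohort_schema <- function(comorbidities = NULL) {
  structure(list(
    patient_id = "patient_id",
    sex        = "sex",
    age        = "age",
    bmi        = "bmi",
    glucose    = setNames(.glu_cols(), OGTT_TIMES),
    insulin    = setNames(.ins_cols(), OGTT_TIMES),
    uric_acid  = "uric_acid",
    hba1c      = "hba1c",
    cohort_id  = "cohort_id",
    comorbidities = comorbidities
  ), class = "cohort_schema")
}

## token table for comorbidity states (round-trip safe)
.COMORBIDITY_TOKENS <- setNames(
  c("present", "present", "present", "absent", "absent", "absent",
    "unknown", "unknown", "unknown"),
  c("1", "present", "yes", "0", "absent", "no", "unknown", "NA", "")
)

.parse_comorbidity <- function(x, col) {
  x[is.na(x)] <- ""
  tok <- .COMORBIDITY_TOKENS[trimws(x)]
  if (anyNA(tok)) {
    bad <- which(is.na(tok))
    .err(sprintf("column '%s': unrecognized comorbidity state '%s' at row(s) %s",
                 col, x[bad[1]], paste(head(bad, 5), collapse = ", ")),
         "obty_error_validation")
  }
  factor(unname(tok), levels = c("present", "absent", "unknown"))
}

.parse_numeric <- function(x, col, required = FALSE) {
  x <- trimws(x)
  miss <- is.na(x) | x == "" | x == "NA"
  out <- rep(NA_real_, length(x))
  suppressWarnings(out[!miss] <- as.numeric(x[!miss]))
  bad <- !miss & is.na(out)
  if (any(bad)) {
    .err(sprintf("column '%s': malformed numeric value '%s' at row(s) %s",
                 col, x[which(bad)[1]], paste(head(which(bad), 5), collapse = ", ")),
         "obty_error_validation")
  }
  if (required && any(miss)) {
    .err(sprintf("column '%s': missing value at row(s) %s",
                 col, paste(head(which(miss), 5), collapse = ", ")),
         "obty_error_validation")
  }
  out
}

.check_range <- function(x, col, lower = 0, upper = Inf, strict = TRUE) {
  bad <- !is.na(x) & if (strict) (x <= lower | x >= upper) else (x < lower | x > upper)
  if (any(bad)) {
    .err(sprintf("column '%s': %d value(s) outside (%g, %g) at row(s) %s",
                 col, sum(bad), lower, upper,
                 paste(head(which(bad), 5), collapse = ", ")),
         "obty_error_validation")
  }
  invisible(x)
}

#' Construct a validated cohort table
#'
#' Builds the canonical in-memory cohort representation from a data frame
#' whose columns already use the canonical names (see [cohort_schema()]).
#' Validation is total: unit-range violations, duplicate patient ids, and
#' unparseable cells raise classed errors naming the offending rows; nothing
#' is silently coerced. Missing OGTT cells are `NA` (zeros are values, never
#' missing).
#'
#' @param df Data frame with canonical columns.
#' @param comorbidities Character vector of comorbidity column names (factors
#'   or tokens `present`/`absent`/`unknown`, also accepting `1`/`0`).
#' @param provenance Free-text source tag.
#' @return A `cohort_table` (a data frame with attributes `comorbidities` and
#'   `provenance`).
#' @export
as_cohort <- function(df, comorbidities = character(), provenance = "unspecified") {
  required <- c("patient_id", "sex", "age", "bmi", .glu_cols(), .ins_cols(), "uric_acid")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    .err(paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
         "obty_error_schema")
  }
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    dup <- unique(df$patient_id[duplicated(df$patient_id)])
    .err(paste0("patient_id not unique within cohort: ", paste(head(dup, 5), collapse = ", ")),
         "obty_error_integrity")
  }
  sex <- trimws(as.character(df$sex))
  if (any(is.na(sex) | !(sex %in% c("male", "female")))) {
    bad <- which(is.na(sex) | !(sex %in% c("male", "female")))
    .err(sprintf("column 'sex': value must be 'male' or 'female' (mandatory); offending row(s) %s",
                 paste(head(bad, 5), collapse = ", ")), "obty_error_validation")
  }
  df$sex <- factor(sex, levels = c("male", "female"))
  for (col in .glu_cols()) {
    df[[col]] <- as.numeric(df[[col]])
    .check_range(df[[col]], col, 0, 50)
  }
  for (col in .ins_cols()) {
    df[[col]] <- as.numeric(df[[col]])
    .check_range(df[[col]], col, 0, Inf)
  }
  df$uric_acid <- as.numeric(df$uric_acid)
  .check_range(df$uric_acid, "uric_acid", 0, Inf)
  df$age <- as.numeric(df$age)
  .check_range(df$age, "age", 0, 150)
  df$bmi <- as.numeric(df$bmi)
  .check_range(df$bmi, "bmi", 0, Inf)
  if (is.null(df$hba1c)) df$hba1c <- NA_real_ else df$hba1c <- as.numeric(df$hba1c)
  if (is.null(df$cohort_id)) df$cohort_id <- provenance
  df$cohort_id <- as.character(df$cohort_id)
  for (col in comorbidities) {
    if (is.null(df[[col]])) .err(paste0("missing comorbidity column: ", col), "obty_error_schema")
    if (!is.factor(df[[col]]) ||
        !identical(levels(df[[col]]), c("present", "absent", "unknown"))) {
      df[[col]] <- .parse_comorbidity(as.character(df[[col]]), col)
    }
  }
  order_cols <- c("patient_id", "sex", "age", "bmi", .glu_cols(), .ins_cols(),
                  "uric_acid", "hba1c", "cohort_id", comorbidities)
  df <- df[, order_cols]
  rownames(df) <- NULL
  structure(df,
            comorbidities = comorbidities,
            provenance = provenance,
            class = c("cohort_table", "data.frame"))
}

#' List the comorbidity columns of a cohort
#'
#' @param cohort A `cohort_table`.
#' @return Character vector of comorbidity column names.
#' @export
comorbidity_names <- function(cohort) attr(cohort, "comorbidities")

#' Read a cohort table from a delimited text file
#'
#' Reads a CSV or TSV cohort export (delimiter auto-detected between comma and
#' tab from the header line) and validates it against the schema. Missing
#' OGTT cells (empty string or `NA`) become missing entries, never zeros;
#' malformed numeric cells, duplicate patient ids and unit-range violations
#' raise classed errors with row/column context.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema A [cohort_schema()] mapping semantic fields to column names.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  if (!file.exists(path)) .err(paste0("file not found: ", path), "obty_error_io")
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- read.delim(path, sep = sep, colClasses = "character",
                    check.names = FALSE, na.strings = NULL,
                    stringsAsFactors = FALSE)
  mapped <- c(schema$patient_id, schema$sex, schema$age, schema$bmi,
              schema$glucose, schema$insulin, schema$uric_acid)
  missing_cols <- setdiff(mapped, names(raw))
  if (length(missing_cols)) {
    .err(paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
         "obty_error_schema")
  }
  optional <- c(schema$hba1c, schema$cohort_id)
  comorb_cols <- schema$comorbidities
  if (is.null(comorb_cols)) {
    comorb_cols <- setdiff(names(raw), c(mapped, optional))
  }
  df <- data.frame(patient_id = raw[[schema$patient_id]],
                   sex = raw[[schema$sex]],
                   stringsAsFactors = FALSE)
  df$age <- .parse_numeric(raw[[schema$age]], schema$age)
  df$bmi <- .parse_numeric(raw[[schema$bmi]], schema$bmi)
  for (i in seq_along(OGTT_TIMES)) {
    df[[.glu_cols()[i]]] <- .parse_numeric(raw[[schema$glucose[i]]], schema$glucose[i])
    df[[.ins_cols()[i]]] <- .parse_numeric(raw[[schema$insulin[i]]], schema$insulin[i])
  }
  df$uric_acid <- .parse_numeric(raw[[schema$uric_acid]], schema$uric_acid)
  df$hba1c <- if (schema$hba1c %in% names(raw)) {
    .parse_numeric(raw[[schema$hba1c]], schema$hba1c)
  } else NA_real_
  df$cohort_id <- if (schema$cohort_id %in% names(raw)) {
    raw[[schema$cohort_id]]
  } else basename(path)
  for (col in comorb_cols) df[[col]] <- .parse_comorbidity(raw[[col]], col)
  as_cohort(df, comorbidities = comorb_cols, provenance = path)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(c))` reproduces `c`
#' field for field. Comorbidity states are written as the tokens
#' `present`/`absent`/`unknown`; missing numeric cells as empty strings.
#'
#' @param cohort A `cohort_table`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$sex <- as.character(out$sex)
  for (col in comorbidity_names(cohort)) out[[col]] <- as.character(out[[col]])
  tryCatch(write.csv(out, path, row.names = FALSE, na = ""),
           error = function(e) .err(paste0("cannot write ", path, ": ",
                                           conditionMessage(e)), "obty_error_io"))
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d patients (%d male, %d female), provenance: %s\n",
              nrow(x), sum(x$sex == "male"), sum(x$sex == "female"),
              attr(x, "provenance")))
  cat("comorbidities:", paste(comorbidity_names(x), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
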