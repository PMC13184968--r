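# Minimal OOXML spreadsheet layer.
#
# Reading goes through readxl. Writing is done here: the dialect only ever
# needs text cells, so worksheets are emitted with inline strings and the
# archive is zipped with fixed entry timestamps, making output byte-stable —
# a property the schema/template writers and the fixture generator rely on.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

col_letter <- function(j) {
  s <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    s <- paste0(LETTERS[r + 1], s)
    j <- (j - 1) %/% 26
  }
  s
}

worksheet_xml <- function(df) {
  stopifnot(is.data.frame(df))
  mat <- rbind(names(df), as.matrix(as.data.frame(lapply(df, as.character),
                                                  stringsAsFactors = FALSE,
                                                  check.names = FALSE)))
  if (ncol(df) == 0) mat <- matrix(character(0), nrow = 0, ncol = 0)
  rows <- character(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    cells <- character(0)
    for (j in seq_len(ncol(mat))) {
      v <- mat[i, j]
      if (is.na(v) || !nzchar(v)) next
      cells <- c(cells, sprintf(
        '<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
        col_letter(j), i, xml_escape(v)))
    }
    rows[i] <- sprintf('<row r="%d">%s</row>', i, paste(cells, collapse = ""))
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
}

#' Write a list of data frames as an XLSX workbook
#'
#' All cells are written as text (inline strings). Output is byte-stable:
#' writing the same sheets twice yields identical files.
#'
#' @param sheets named list of data frames; names become sheet names
#' @param path output file path (.xlsx)
#' @return the path, invisibly
#' @export
write_xlsx_sheets <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) == 0 || !is.null(names(sheets)))
  n <- length(sheets)
  if (n == 0) stop_fermeta("workbook must contain at least one sheet", "fermeta_io_error")
  tmp <- tempfile("xlsxw")
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  on.exit(unlink(tmp, recursive = TRUE))

  ct <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  seq_len(n)), collapse = ""),
    '</Types>')
  writeLines(ct, file.path(tmp, "[Content_Types].xml"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(tmp, "_rels", ".rels"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships"><sheets>',
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  xml_escape(names(sheets)), seq_len(n), seq_len(n)), collapse = ""),
    '</sheets></workbook>'), file.path(tmp, "xl", "workbook.xml"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(n), seq_len(n)), collapse = ""),
    '</Relationships>'), file.path(tmp, "xl", "_rels", "workbook.xml.rels"))
  for (i in seq_len(n)) {
    writeLines(worksheet_xml(as.data.frame(sheets[[i]])),
               file.path(tmp, "xl", "worksheets", sprintf("sheet%d.xml", i)))
  }
  files <- list.files(tmp, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  # fixed mtimes so the zip archive is byte-identical across runs
  Sys.setFileTime(file.path(tmp, files), "2000-01-01 00:00:00 UTC")
  path <- file.path(normalizePath(dirname(path), mustWork = TRUE), basename(path))
  if (file.exists(path)) unlink(path)
  zip::zip(path, files, root = tmp, include_directories = FALSE, mode = "mirror")
  invisible(path)
}

#' Read every sheet of a workbook as text
#'
#' @param path workbook path
#' @return named list of tibbles, all columns character
#' @export
read_xlsx_sheets <- function(path) {
  if (!file.exists(path)) {
    stop_fermeta(sprintf("workbook not found: %s", path), "fermeta_io_error")
  }
  sheets <- readxl::excel_sheets(path)
  out <- lapply(sheets, function(s) {
    df <- readxl::read_xlsx(path, sheet = s, col_types = "text",
                            .name_repair = "minimal")
    tibble::as_tibble(df, .name_repair = "minimal")
  })
  names(out) <- sheets
  out
}
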