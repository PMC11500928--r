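# Minimal Office Open XML workbook writer: one sheet, every cell an inline
# string. Sufficient for the unblinded results table; `readxl` (or any
# spreadsheet application) reads it back.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  # literal CR would be normalized away by XML parsers; encode it
  gsub("\r", "&#13;", x, fixed = TRUE)
}

xlsx_col_letter <- function(j) {
  out <- ""
  while (j > 0L) {
    r <- (j - 1L) %% 26L
    out <- paste0(LETTERS[r + 1L], out)
    j <- (j - 1L) %/% 26L
  }
  out
}

write_xlsx_minimal <- function(df, path, sheet = "Results") {
  cells <- rbind(colnames(df), as.matrix(df))
  cells[is.na(cells)] <- ""
  nr <- nrow(cells); nc <- ncol(cells)
  col_ref <- vapply(seq_len(nc), xlsx_col_letter, "")

  rows_xml <- vapply(seq_len(nr), function(i) {
    cs <- vapply(seq_len(nc), function(j) {
      sprintf('<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
              col_ref[j], i, xml_escape(cells[i, j]))
    }, "")
    sprintf('<row r="%d">%s</row>', i, paste0(cs, collapse = ""))
  }, "")

  sheet_xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', paste0(rows_xml, collapse = ""), '</sheetData></worksheet>'
  )
  workbook_xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    sprintf('<sheets><sheet name="%s" sheetId="1" r:id="rId1"/></sheets></workbook>',
            xml_escape(sheet))
  )
  wb_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" ',
    'Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" ',
    'Target="worksheets/sheet1.xml"/></Relationships>'
  )
  root_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" ',
    'Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" ',
    'Target="xl/workbook.xml"/></Relationships>'
  )
  content_types <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ',
    'ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ',
    'ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>'
  )

  stage <- tempfile("xlsxstage")
  dir.create(file.path(stage, "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "xl", "worksheets"), recursive = TRUE)
  parts <- c("[Content_Types].xml" = content_types,
             "_rels/.rels" = root_rels,
             "xl/workbook.xml" = workbook_xml,
             "xl/_rels/workbook.xml.rels" = wb_rels,
             "xl/worksheets/sheet1.xml" = sheet_xml)
  for (p in names(parts)) {
    writeLines(parts[[p]], file.path(stage, p), useBytes = TRUE)
    # fixed timestamps keep repeated exports byte-identical
    Sys.setFileTime(file.path(stage, p), as.POSIXct("2020-01-01 00:00:00", tz = "UTC"))
  }
  if (file.exists(path)) unlink(path)
  # zip() changes directory to `root`; the target path must be absolute
  abs_path <- file.path(normalizePath(dirname(path), mustWork = TRUE), basename(path))
  zip::zip(abs_path, files = names(parts),
           root = stage, include_directories = FALSE, mode = "mirror")
  unlink(stage, recursive = TRUE)
  invisible(path)
}
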