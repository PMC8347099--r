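# Builds a minimal single-sheet XLSX (inline strings) so the xlsx
# interaction-table adapter can be exercised on a synthetic fixture
# without shipping a binary file. Requires the 'zip' package.
make_xlsx_fixture <- function(path, header, rows) {
  dir <- tempfile()
  dir.create(file.path(dir, "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "worksheets"), recursive = TRUE)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>'), file.path(dir, "[Content_Types].xml"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(dir, "_rels", ".rels"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets></workbook>'),
    file.path(dir, "xl", "workbook.xml"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    '</Relationships>'), file.path(dir, "xl", "_rels", "workbook.xml.rels"))
  cell <- function(v) paste0('<c t="inlineStr"><is><t>', v, '</t></is></c>')
  row_xml <- vapply(c(list(header), rows), function(r)
    paste0("<row>", paste(vapply(r, cell, character(1)), collapse = ""),
           "</row>"), character(1))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', row_xml, '</sheetData></worksheet>'),
    file.path(dir, "xl", "worksheets", "sheet1.xml"))
  if (!grepl("^(/|[A-Za-z]:)", path)) path <- file.path(getwd(), path)
  zip::zip(path,
           c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
             "xl/_rels/workbook.xml.rels", "xl/worksheets/sheet1.xml"),
           root = dir)
  path
}
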