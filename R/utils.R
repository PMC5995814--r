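# shared input handling: accept a file path or a character vector of lines
input_lines <- function(file) {
  if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    return(readLines(file, warn = FALSE))
  }
  out <- unlist(strsplit(as.character(file), "\n", fixed = TRUE))
  if (is.null(out)) character(0) else out
}
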