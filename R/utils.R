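# Internal helpers shared across modules.

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# letters accepted in each moltype (IUPAC, uppercase)
NT_ALPHABET <- c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K",
                 "M", "B", "D", "H", "V")
AA_ALPHABET_EXT <- c(AMINO_ACIDS, "X", "B", "Z", "U", "O")

cx_stop <- function(class, msg, ..., call. = FALSE) {
  cond <- structure(
    class = c(class, "coralox_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

# run code with a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# accept a protein_candidate, seq_record (protein) or plain string; return residues
as_residues <- function(x) {
  if (inherits(x, "protein_candidate")) return(x$residues)
  if (inherits(x, "seq_record")) {
    if (x$moltype != "protein")
      cx_stop("coralox_type_error", "expected a protein sequence, got nucleotide")
    return(x$residues)
  }
  if (is_string(x)) return(toupper(x))
  cx_stop("coralox_type_error", "cannot interpret object as a protein sequence")
}

seq_label <- function(x, default = "query") {
  if (inherits(x, "protein_candidate")) x$parent_id
  else if (inherits(x, "seq_record")) x$id
  else default
}
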