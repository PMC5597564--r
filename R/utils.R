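## Small shared helpers.

## AutoDock atom type code -> chemical element symbol.
typeToElement <- function(type) {
  map <- c(H = "H", HD = "H", HS = "H", C = "C", A = "C", N = "N", "NA" = "N",
           NS = "N", OA = "O", OS = "O", F = "F", P = "P", S = "S", SA = "S",
           Cl = "Cl", CL = "Cl", Br = "Br", BR = "Br", I = "I", Ca = "Ca",
           CA = "Ca", Mg = "Mg", MG = "Mg", Zn = "Zn", ZN = "Zn", Fe = "Fe",
           FE = "Fe", Mn = "Mn", MN = "Mn")
  out <- unname(map[type])
  miss <- is.na(out)
  out[miss] <- substr(type[miss], 1, 1)
  out
}

## Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Polynomial rolling hash of a character vector, hex string.  Used to stamp
## result files with a configuration fingerprint.
configHash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
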