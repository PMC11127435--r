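# Internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so library functions never disturb user simulations.
.withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Accept either a SceneParams object or a plain named list and return a
# plain list; list input bypasses the >=32 grid validity so that small
# hand-checkable grids remain usable in low-level calls.
.paramsList <- function(params) {
  if (is(params, "SceneParams")) {
    list(gridW = params@gridW, gridH = params@gridH, sigma = params@sigma,
         limbWidth = params@limbWidth, nPersons = params@nPersons,
         noiseSd = params@noiseSd, seed = params@seed)
  } else {
    defaults <- list(gridW = 128L, gridH = 128L, sigma = 6, limbWidth = 4,
                     nPersons = 1L, noiseSd = 1, seed = 1L)
    utils::modifyList(defaults, as.list(params))
  }
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# md5 of an in-memory object via its canonical JSON rendering
.jsonHash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
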