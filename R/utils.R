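# internal helpers shared across modules

# evaluate `code` under a fixed seed without disturbing the caller's RNG state;
# a NULL seed means "use the current RNG stream"
with_seed_ <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), force(code))
  }
}

# deterministic per-component sub-seed derived from a master seed and a label,
# kept strictly inside 32-bit integer range
substream <- function(seed, label) {
  if (is.null(seed)) {
    return(NULL)
  }
  h <- sum(utf8ToInt(label) * ((seq_len(nchar(label)) %% 13) + 1))
  as.integer((as.numeric(seed) %% 1e6) * 2039 + (h %% 97943) * 7919) %%
    2147483563L + 1L
}

# population standard deviation (divide by n, not n - 1); documented choice so
# normalization tests are exact
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

standardize <- function(x) {
  s <- pop_sd(x)
  if (s == 0) {
    abort("cannot standardize a constant vector")
  }
  (x - mean(x)) / s
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == round(x) && x >= 0
}
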