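# small architectures and memoized trained models shared across test files

small_arch <- function(d_ext = 2L, d_readout = 1L, n_kc = 60L)
  mb_arch(n_mbon = 6L, n_dan = 6L, n_fbn = 18L, n_kc = n_kc,
          d_ext = d_ext, d_readout = d_readout)

tiny_arch <- function(d_ext = 2L)
  mb_arch(n_mbon = 4L, n_dan = 4L, n_fbn = 8L, n_kc = 20L, d_ext = d_ext)

random_params <- function(arch = tiny_arch(), seed = 1, ...) {
  set.seed(seed)
  initialize_parameters(arch, ...)
}

# train-once cache: desk-scale models reused across acceptance checks
.model_cache <- new.env(parent = emptyenv())

cached_model <- function(key, builder) {
  if (!exists(key, envir = .model_cache))
    assign(key, builder(), envir = .model_cache)
  get(key, envir = .model_cache)
}

full_mixture_model <- function(recurrent = TRUE)
  cached_model(paste0("mixture_full_", recurrent), function()
    mb_fit("mixture", n_epochs = if (recurrent) 2000 else 1000,
           recurrent = recurrent, seed = 301))

small_mixture_model <- function()
  cached_model("mixture_small", function()
    mb_fit("mixture", arch = small_arch(), n_epochs = 1200, seed = 7))

small_novelty_model <- function()
  cached_model("novelty_small", function()
    mb_fit("novelty", arch = small_arch(d_readout = 2L), n_epochs = 600,
           seed = 7))

small_state_model <- function()
  cached_model("state_small", function()
    mb_fit("state", arch = small_arch(d_ext = 5L), n_epochs = 250,
           batch_size = 15, seed = 7))

small_continual_model <- function(beta_on = TRUE)
  cached_model(paste0("continual_", beta_on), function()
    mb_fit("continual", arch = small_arch(), n_epochs = 400,
           batch_size = 15, carryover_anneal_epochs = 200,
           potentiation = beta_on, seed = 7))
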