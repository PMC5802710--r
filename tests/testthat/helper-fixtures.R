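# shared fixture builders; everything is generated in code, no stored data

# minimal single-measure configuration with a small reference group allowed
config1 <- function(direction = "flag-low", ...) {
  profiling_config(measures = list(measure_spec("m1", "cm", direction)),
                   k = 1L, min_control_n = 3L, ...)
}

# configuration with p generic measures m1..mp
config_generic <- function(p = 7L, k = 4L, directions = rep("flag-low", p), ...) {
  profiling_config(
    measures = lapply(seq_len(p), function(i)
      measure_spec(paste0("m", i), "cm", directions[i])),
    k = k, min_control_n = 3L, ...)
}

# behavior table from a matrix of measure values
make_table <- function(values, group = "control", ids = NULL, config) {
  values <- as.matrix(values)
  colnames(values) <- measure_names(config)[seq_len(ncol(values))]
  df <- data.frame(
    animal_id = if (is.null(ids)) sprintf("a%03d", seq_len(nrow(values))) else ids,
    group = rep_len(group, nrow(values)),
    stringsAsFactors = FALSE)
  as_behavior_table(cbind(df, as.data.frame(values)), config)
}

# random positive table under a fixed seed
random_table <- function(n, config, groups = "control", seed = 1) {
  set.seed(seed)
  p <- length(measure_names(config))
  make_table(matrix(rlnorm(n * p), n, p),
             group = rep_len(groups, n), config = config)
}
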