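# Fixture builders shared across the suite. Everything is generated in code;
# sizes are kept small so single tests stay fast.

# random symmetric matrix with zero diagonal
random_symmetric <- function(n) {
  m <- matrix(rnorm(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# random connectome set with iid normal edges
random_set <- function(n_subjects, n_tasks, n_nodes) {
  ne <- edge_count(n_nodes)
  task_connectome_set(
    array(rnorm(n_subjects * n_tasks * ne), dim = c(n_subjects, n_tasks, ne)),
    sprintf("s%03d", seq_len(n_subjects)),
    paste0("task", seq_len(n_tasks)), n_nodes)
}

# small cohort config; desk-scale overrides of the study defaults
small_config <- function(n_nodes = 40, n_tasks = 3,
                         group_sizes = c(HC = 30, SCZ = 14, BPAD = 14, ADHD = 14),
                         n_signal_edges = 40, n_group_edges = 20,
                         n_motion_edges = 30, ...) {
  cohort_config(group_sizes = group_sizes, n_nodes = n_nodes,
                n_tasks = n_tasks, n_signal_edges = n_signal_edges,
                n_group_edges = n_group_edges, n_motion_edges = n_motion_edges,
                ...)
}

# a config with no planted structure at all
null_config <- function(...) {
  small_config(effect_size = 0,
               group_deltas = c(HC = 0, SCZ = 0, BPAD = 0, ADHD = 0),
               motion_edge_coeff = 0, motion_trait_corr = 0, ...)
}

# round-robin canonical network map
rr_netmap <- function(n_nodes) network_map(rep_len(canonical_networks, n_nodes))
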