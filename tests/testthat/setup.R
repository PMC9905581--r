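# Dense linear algebra in the samplers is single-thread-optimal at the
# matrix sizes used here; cap BLAS/OpenMP threads so multithreaded BLAS
# builds do not oversubscribe the CPU.
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1",
           GOTO_NUM_THREADS = "1")
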