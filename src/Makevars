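# Interpolation and separable-convolution kernels dominate runtime;
# loop-unrolling-friendly optimisation is worth it here.
PKG_CXXFLAGS = -O3 -funroll-loops
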