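# -fno-math-errno lets the compiler vectorize the sqrt in the Adam update
# (sqrtf otherwise implies an errno side effect that blocks SIMD).
PKG_CXXFLAGS = -fno-math-errno
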