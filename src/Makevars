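# Build with the system toolchain: objects must bind to the C library the
# dynamic loader resolves at run time (the bundled cross toolchain targets a
# newer glibc than the one the loader provides).
override CXX = /usr/bin/g++ -std=gnu++17
override CXX17 = /usr/bin/g++
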