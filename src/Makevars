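# The monodomain solver is this package's hot path; compile it with full
# optimization for the build machine (the package is always compiled from
# source), appended so it takes precedence over the default -O2.
all: $(SHLIB)

tp06.o: tp06.cpp
	$(CXX) $(ALL_CPPFLAGS) $(ALL_CXXFLAGS) -O3 -march=native -c tp06.cpp -o $@
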