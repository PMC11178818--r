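# Stimulation-site frame on the otic capsule, above the lateral semicircular
# canal, in global skull coordinates.  Versors printed to 3 decimals; they are
# re-orthonormalized on load (Gram-Schmidt anchored on x_hat).
origin_mm: [-45.92, 6.24, -25.28]
x_hat: [0.004, -0.918, 0.397]
y_hat: [-0.270, -0.383, -0.884]
z_hat: [0.963, -0.104, -0.249]
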