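gene	class	role
ARR3	cone	recovery
SWS1	cone	activation
LWS	cone	activation
PDE6H	cone	activation
PDE6C	cone	activation
GNGT2	cone	activation
CNGB3	cone	activation
CNGA3	cone	activation
GNB3	cone	activation
GRK7	cone	recovery
CNGA1	rod	activation
CNGB1	rod	activation
PDE6B	rod	activation
PDE6A	rod	activation
GNGT1	rod	activation
RH1	rod	activation
SLC24A1	rod	activation
GRK1	rod	recovery
RCVRN	both	recovery
RGS9	both	recovery
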