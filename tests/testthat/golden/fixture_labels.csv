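cell_id,cluster
cell_0001,2
cell_0002,3
cell_0003,3
cell_0004,2
cell_0005,2
cell_0006,2
cell_0007,1
cell_0008,1
cell_0009,2
cell_0010,3
cell_0011,1
cell_0012,2
cell_0013,3
cell_0014,3
cell_0015,1
cell_0016,2
cell_0017,2
cell_0018,1
cell_0019,1
cell_0020,3
cell_0021,1
cell_0022,1
cell_0023,3
cell_0024,3
cell_0025,2
cell_0026,2
cell_0027,2
cell_0028,2
cell_0029,1
cell_0030,1
cell_0031,1
cell_0032,2
cell_0033,3
cell_0034,3
cell_0035,1
cell_0036,3
cell_0037,2
cell_0038,3
cell_0039,2
cell_0040,1
cell_0041,2
cell_0042,2
cell_0043,3
cell_0044,1
cell_0045,1
cell_0046,1
cell_0047,3
cell_0048,2
cell_0049,1
cell_0050,3
cell_0051,3
cell_0052,3
cell_0053,3
cell_0054,1
cell_0055,2
cell_0056,2
cell_0057,1
cell_0058,3
cell_0059,1
cell_0060,3
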