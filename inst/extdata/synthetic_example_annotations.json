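{"slideA_img1.jpg":{"filename":"slideA_img1.jpg","size":-1,"width":512,"height":384,"regions":[{"shape_attributes":{"name":"polygon","all_points_x":[5,500,505,10],"all_points_y":[60,40,330,350]},"region_attributes":{"class":"root"}},{"shape_attributes":{"name":"polygon","all_points_x":[226.5,210.4,199.8,189.7,185.4,216.8],"all_points_y":[274.4,288.8,271.1,271,259.9,255.7]},"region_attributes":{"class":"exH"}},{"shape_attributes":{"name":"polygon","all_points_x":[144.1,148.5,147.9,135.2,149.4,154.5],"all_points_y":[205.6,199.8,183.9,180.5,161,167]},"region_attributes":{"class":"ves"}},{"shape_attributes":{"name":"polygon","all_points_x":[190.5,182.7,159.3,157.4,165.7,191.4,198.4,184.6],"all_points_y":[158.9,161.9,162.1,123.7,121.5,123,131.4,138.3]},"region_attributes":{"class":"arb"}},{"shape_attributes":{"name":"polygon","all_points_x":[244.5,236.9,235.2,231,228.8,218.2,216.8],"all_points_y":[126.3,135.1,142.4,136.4,131.1,104.9,103.2]},"region_attributes":{"class":"arb"}},{"shape_attributes":{"name":"polygon","all_points_x":[285.1,275.3,279.1,292.5,315.5],"all_points_y":[339.6,304.9,297.3,307.4,312.2]},"region_attributes":{"class":"ves"}},{"shape_attributes":{"name":"polygon","all_points_x":[94,88.9,78.1,90.9,92.1,110],"all_points_y":[61.7,64.1,40.6,21.3,32.6,38.3]},"region_attributes":{"class":"exH"}}]},"slideA_img2.jpg":{"filename":"slideA_img2.jpg","size":-1,"width":512,"height":384,"regions":[{"shape_attributes":{"name":"polygon","all_points_x":[5,500,505,10],"all_points_y":[60,40,330,350]},"region_attributes":{"class":"root"}},{"shape_attributes":{"name":"polygon","all_points_x":[165.4,137.4,127.5,118.9,132.5,152.4],"all_points_y":[335.8,336.1,342.5,318.4,306.2,328]},"region_attributes":{"class":"arb"}},{"shape_attributes":{"name":"polygon","all_points_x":[90.2,71.5,77,54.4,79.5,94.7],"all_points_y":[131.2,121.2,116.6,116.5,82.6,94.4]},"region_attributes":{"class":"sp"}},{"shape_attributes":{"name":"polygon","all_points_x":[268.3,284.2,266.3,233.8,228.7,249.3,251.4,251.4],"all_points_y":[319,325.3,323.5,323.4,323,313.6,311.8,306.9]},"region_attributes":{"class":"sp"}},{"shape_attributes":{"name":"polygon","all_points_x":[101.6,58.1,83.2,85.8,84.8],"all_points_y":[91.6,72.7,68.9,71.8,79.2]},"region_attributes":{"class":"sp"}},{"shape_attributes":{"name":"polygon","all_points_x":[316.8,310.8,313.5,311.9,334.1,341,347.9],"all_points_y":[121.6,106.9,102.7,84.8,82,74.6,73.7]},"region_attributes":{"class":"sp"}}]}}
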