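- title: "Dining out on DASH"
  link: "https://videos.example.org/dash/dining-out"
- title: "Reading nutrition labels"
  link: "https://videos.example.org/dash/labels"
- title: "Smart shopping for DASH"
  link: "https://videos.example.org/dash/shopping"
- title: "Cooking with less salt"
  link: "https://videos.example.org/dash/less-salt"
- title: "Snacking the DASH way"
  link: "https://videos.example.org/dash/snacks"
- title: "DASH on a budget"
  link: "https://videos.example.org/dash/budget"
- title: "Breakfast ideas for DASH"
  link: "https://videos.example.org/dash/breakfast"
- title: "Whole grains made easy"
  link: "https://videos.example.org/dash/whole-grains"
- title: "Fruits and vegetables every day"
  link: "https://videos.example.org/dash/produce"
- title: "Dairy choices on DASH"
  link: "https://videos.example.org/dash/dairy"
- title: "Staying on DASH while traveling"
  link: "https://videos.example.org/dash/travel"
- title: "Keeping DASH going long term"
  link: "https://videos.example.org/dash/maintenance"
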